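# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Small homogeneous box system: 9^3 = 729 nodes, fast to assemble, large
# enough for the loop to show its schedule.
small_system <- function() {
  cached("small_system", {
    mesh <- build_structured_tet_mesh(c(8, 8, 8), 1)
    fem <- assemble_fem(mesh)
    sysmat <- build_system_matrix(fem)
    list(mesh = mesh, fem = fem, sysmat = sysmat)
  })
}

# Full-scale seeded study shared by the acceptance tests (criteria on the
# feasibility bounds and the paired improvement property use the same runs).
acceptance_study <- function() {
  cached("acceptance_study",
         peddrs_study(seeds = 1:5, solvers = c("tikhonov", "dsvd")))
}

# Independent dense Tikhonov oracle: explicit normal equations.
oracle_tikhonov <- function(A, B, lambda) {
  solve(crossprod(A) + lambda * diag(ncol(A)), crossprod(A, B))
}

# Independent DSVD oracle: explicit filter-factor sum over the thin SVD.
oracle_dsvd <- function(A, B, lambda) {
  sv <- svd(A)
  x <- numeric(ncol(A))
  for (i in seq_along(sv$d)) {
    if (sv$d[i] <= 1e-12 * sv$d[1]) next
    x <- x + (sv$d[i] / (sv$d[i] + lambda)) *
      (sum(sv$u[, i] * B) / sv$d[i]) * sv$v[, i]
  }
  x
}

# Independent lasso oracle: cyclic coordinate descent on
# ||Ax - B||^2 + lambda ||x||_1.
oracle_lasso_cd <- function(A, B, lambda, sweeps = 2000) {
  x <- numeric(ncol(A))
  cn <- colSums(A^2)
  r <- B - A %*% x
  for (s in seq_len(sweeps)) {
    for (j in seq_len(ncol(A))) {
      rj <- r + A[, j] * x[j]
      cj <- sum(A[, j] * rj)
      xj <- sign(cj) * max(abs(cj) - lambda / 2, 0) / cn[j]
      r <- rj - A[, j] * xj
      x[j] <- xj
    }
  }
  x
}

lasso_objective <- function(A, B, lambda, x)
  sum((A %*% x - B)^2) + lambda * sum(abs(x))

# Manufactured-solution FEM error on a homogeneous cube of side L:
# Phi(x,y,z) = phi(x) phi(y) phi(z), phi(t) = cos(k (t - L/2)) with k
# chosen so phi satisfies the homogeneous Robin condition at 0 and L.
mms_error <- function(spacing, L = 8, tissue = "Muscle", rf = 0.431) {
  opt <- tissue_optics()[tissue, ]
  D <- diffusion_coefficient(opt)
  Fb <- boundary_factor(rf)
  k <- stats::uniroot(function(k) cos(k * L / 2) - 2 * Fb * D * k * sin(k * L / 2),
                      c(1e-6, pi / L - 1e-6))$root
  mesh <- build_structured_tet_mesh(c(L, L, L), spacing)
  fem <- assemble_fem(mesh, rf = rf)
  phi <- function(t) cos(k * (t - L / 2))
  exact <- phi(mesh$nodes[, 1]) * phi(mesh$nodes[, 2]) * phi(mesh$nodes[, 3])
  s <- (3 * D * k^2 + opt$mu_a) * exact
  num <- solve_fem(fem, s)
  err <- num - exact
  # L2 norms through the consistent mass matrix
  sqrt(sum(err * as.numeric(fem$M %*% err))) /
    sqrt(sum(exact * as.numeric(fem$M %*% exact)))
}

# Brute-force ROI containment oracle: per-node loop in the box frame.
brute_force_in_box <- function(nodes, box) {
  inside <- logical(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    d <- nodes[i, ] - box$center
    loc <- as.numeric(t(box$axes) %*% d)
    inside[i] <- all(abs(loc) <= box$half_lengths)
  }
  which(inside)
}

random_spd3 <- function() {
  m <- matrix(rnorm(9), 3)
  crossprod(m)
}
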