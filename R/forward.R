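#' Assemble the FEM diffusion system
#'
#' Discretizes the diffusion approximation
#' \deqn{-\nabla\cdot D\nabla\Phi + \mu_a \Phi = S}
#' with the Robin boundary condition \eqn{\Phi + 2FD\,\partial_n\Phi = 0}
#' on a tetrahedral mesh with linear (P1) elements. The system matrix is
#' \deqn{K = \sum_e D_e S_e + \mu_{a,e} M_e + \frac{1}{2F}\sum_f M_f}
#' with per-element stiffness \eqn{S_e}, consistent mass \eqn{M_e} and
#' boundary-triangle surface mass \eqn{M_f}. K is symmetric positive
#' definite whenever every tissue absorbs.
#'
#' @param mesh a [tet_mesh()] whose `region` labels all appear in
#'   `optics`.
#' @param optics optics table (rows = tissue names) as returned by
#'   [tissue_optics()].
#' @param rf internal reflection coefficient, see [boundary_factor()].
#' @param mus_interpretation passed to [diffusion_coefficient()].
#' @return an object of class `fem_system`: `K` (sparse symmetric),
#'   `M` (consistent mass), `boundary_nodes`, `F`, `rf`, `mesh`.
#' @export
assemble_fem <- function(mesh, optics = tissue_optics(), rf = 0.431,
                         mus_interpretation = c("reduced", "raw")) {
  mus_interpretation <- match.arg(mus_interpretation)
  missing_t <- setdiff(unique(mesh$region), rownames(optics))
  if (length(missing_t))
    stop("no optics for tissue(s): ", paste(missing_t, collapse = ", "))
  n <- nrow(mesh$nodes)
  tets <- mesh$tets
  vol_s <- tet_volumes_signed(mesh$nodes, tets)
  if (any(vol_s <= 0))
    stop("inconsistent element orientation: non-positive tet volume")
  vol <- vol_s

  opt <- optics[mesh$region, , drop = FALSE]
  D_t <- 1 / (3 * (opt$mu_a + if (mus_interpretation == "raw")
    (1 - opt$g) * opt$mu_s_prime else opt$mu_s_prime))
  mua_t <- opt$mu_a

  # P1 barycentric gradients per tet (rows of the inverse edge matrix).
  p1 <- mesh$nodes[tets[, 1L], , drop = FALSE]
  u <- mesh$nodes[tets[, 2L], , drop = FALSE] - p1
  v <- mesh$nodes[tets[, 3L], , drop = FALSE] - p1
  w <- mesh$nodes[tets[, 4L], , drop = FALSE] - p1
  det3 <- 6 * vol_s
  cross3 <- function(a, b)
    cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
          a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
          a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  g2 <- cross3(v, w) / det3
  g3 <- cross3(w, u) / det3
  g4 <- cross3(u, v) / det3
  g1 <- -(g2 + g3 + g4)
  grads <- list(g1, g2, g3, g4)

  nt <- nrow(tets)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  mi <- integer(0); mj <- integer(0); mx <- numeric(0)
  for (i in 1:4) {
    for (j in 1:4) {
      ke <- D_t * vol * rowSums(grads[[i]] * grads[[j]])
      me <- vol * (if (i == j) 1 / 10 else 1 / 20)
      ii <- c(ii, tets[, i]); jj <- c(jj, tets[, j])
      xx <- c(xx, ke + mua_t * me)
      mi <- c(mi, tets[, i]); mj <- c(mj, tets[, j])
      mx <- c(mx, me)
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  M <- Matrix::sparseMatrix(i = mi, j = mj, x = mx, dims = c(n, n))

  # Robin surface term over boundary triangles: (1/2F) * surface mass.
  Fb <- boundary_factor(rf)
  bf <- mesh$boundary_faces
  e1 <- mesh$nodes[bf[, 2L], , drop = FALSE] - mesh$nodes[bf[, 1L], , drop = FALSE]
  e2 <- mesh$nodes[bf[, 3L], , drop = FALSE] - mesh$nodes[bf[, 1L], , drop = FALSE]
  area <- sqrt(rowSums(cross3(e1, e2)^2)) / 2
  bi <- integer(0); bj <- integer(0); bx <- numeric(0)
  for (i in 1:3) {
    for (j in 1:3) {
      bi <- c(bi, bf[, i]); bj <- c(bj, bf[, j])
      bx <- c(bx, area * (if (i == j) 1 / 6 else 1 / 12))
    }
  }
  Kb <- Matrix::sparseMatrix(i = bi, j = bj, x = bx, dims = c(n, n))
  K <- K + Kb / (2 * Fb)
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)

  structure(
    list(K = K, M = M,
         boundary_nodes = sort(unique(as.integer(bf))),
         F = Fb, rf = rf, mesh = mesh),
    class = "fem_system")
}

#' Solve the FEM system for a smooth volumetric source
#'
#' Computes the photon fluence for a nodal source density `s` using the
#' consistent-mass load vector, `K phi = M s`.
#'
#' @param fem a [assemble_fem()] system.
#' @param s nodal source density (length = number of nodes).
#' @return nodal fluence vector.
#' @export
solve_fem <- function(fem, s) {
  as.numeric(Matrix::solve(fem$K, fem$M %*% s))
}

#' Build the boundary-measurement system matrix
#'
#' Column j of A is the restriction to the boundary nodes of
#' \eqn{K^{-1} e_j}: the surface fluence generated by a unit point
#' source at candidate node j (a nodal delta load, i.e. mass-lumped).
#' Since K is symmetric, A is computed row-wise through one sparse
#' Cholesky factorization and |boundary| solves.
#'
#' @param fem a `fem_system` (only `K` and `boundary_nodes` are used).
#' @param candidate_nodes candidate source nodes (columns of A);
#'   defaults to all non-boundary nodes.
#' @return object of class `system_matrix`: `A` (dense M x N matrix),
#'   `row_nodes`, `col_nodes`.
#' @export
build_system_matrix <- function(fem, candidate_nodes = NULL) {
  n <- nrow(fem$K)
  bnd <- fem$boundary_nodes
  if (is.null(candidate_nodes))
    candidate_nodes <- setdiff(seq_len(n), bnd)
  candidate_nodes <- sort(unique(as.integer(candidate_nodes)))
  if (length(candidate_nodes) == 0L) stop("candidate_nodes must be nonempty")
  E <- Matrix::sparseMatrix(i = bnd, j = seq_along(bnd), x = 1,
                            dims = c(n, length(bnd)))
  Y <- tryCatch(Matrix::solve(fem$K, E),
                error = function(e) stop("forward solver failure: ",
                                         conditionMessage(e)))
  A <- t(as.matrix(Y[candidate_nodes, , drop = FALSE]))
  if (any(!is.finite(A))) stop("system matrix contains non-finite entries")
  structure(list(A = A, row_nodes = as.integer(bnd),
                 col_nodes = candidate_nodes),
            class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("system_matrix: %d boundary measurements x %d candidate nodes\n",
              nrow(x$A), ncol(x$A)))
  invisible(x)
}

#' Simulate noisy surface measurements
#'
#' B = A x_true scaled entry-wise by (1 + eps) with eps ~ N(0,
#' noise_level), a multiplicative proxy for CCD shot noise; negative
#' entries are clamped to zero.
#'
#' @param sysmat a [build_system_matrix()] result (or plain matrix).
#' @param x_true source intensities, either over the candidate nodes
#'   (length N) or over all mesh nodes (subset by `col_nodes`).
#' @param noise_level relative Gaussian noise standard deviation, >= 0.
#' @param seed optional RNG seed for reproducibility.
#' @return numeric measurement vector B (length M).
#' @export
simulate_surface_flux <- function(sysmat, x_true, noise_level = 0.05,
                                  seed = NULL) {
  if (!is.finite(noise_level) || noise_level < 0)
    stop("noise_level must be >= 0")
  A <- if (inherits(sysmat, "system_matrix")) sysmat$A else as.matrix(sysmat)
  if (inherits(sysmat, "system_matrix") && length(x_true) != ncol(A))
    x_true <- x_true[sysmat$col_nodes]
  if (length(x_true) != ncol(A)) stop("x_true length does not match A")
  b <- as.numeric(A %*% x_true)
  if (noise_level > 0) {
    if (!is.null(seed)) set.seed(seed)
    b <- b * (1 + stats::rnorm(length(b), 0, noise_level))
  }
  pmax(b, 0)
}
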