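#' Residual norm of an iteration
#'
#' E_L2 = || A[, index_sp] x - B ||_2, the l2 error rate of one
#' reconstruction restricted to its active candidate set.
#'
#' @param A full system matrix (M x N).
#' @param index_sp active column indices.
#' @param x solution on `index_sp`.
#' @param B measurement vector.
#' @return nonnegative scalar.
#' @export
evaluate_l2 <- function(A, index_sp, x, B) {
  if (length(index_sp) == 0L) stop("index_sp must be nonempty")
  sqrt(sum((as.numeric(A[, index_sp, drop = FALSE] %*% x) - B)^2))
}

#' Cosine similarity of an iteration
#'
#' E_Cos = <Ax, B> / (||Ax|| ||B||), with the convention 0 when either
#' vector vanishes. For nonnegative data this lies in [0, 1].
#'
#' @inheritParams evaluate_l2
#' @return scalar in [-1, 1].
#' @export
evaluate_cos <- function(A, index_sp, x, B) {
  ax <- as.numeric(A[, index_sp, drop = FALSE] %*% x)
  na <- sqrt(sum(ax^2)); nb <- sqrt(sum(B^2))
  if (na == 0 || nb == 0) return(0)
  sum(ax * B) / (na * nb)
}

#' Probability weights over completed iterations
#'
#' The residual is an inversely proportional quality measure and the
#' cosine similarity a proportional one, so P_L2(i) is proportional to
#' 1/E_L2(i) and P_Cos(i) to E_Cos(i), each normalized over all
#' completed iterations; the probability weight is their average,
#' P_Err = (P_L2 + P_Cos)/2. Weights are recomputed over the whole
#' history at every refresh. Residuals are floored at 1e-12; if every
#' cosine is zero, P_Cos falls back to uniform.
#'
#' @param e_l2 residual norms, one per iteration.
#' @param e_cos cosine similarities, same length.
#' @return weight vector, nonnegative, summing to 1.
#' @export
probability_weights <- function(e_l2, e_cos) {
  stopifnot(length(e_l2) == length(e_cos), length(e_l2) >= 1L)
  inv <- 1 / pmax(e_l2, 1e-12)
  p_l2 <- inv / sum(inv)
  ec <- pmax(e_cos, 0)
  p_cos <- if (sum(ec) == 0) rep(1 / length(ec), length(ec)) else ec / sum(ec)
  (p_l2 + p_cos) / 2
}

#' Normalized probabilistic source distribution
#'
#' Converts one clamped iteration solution into a discrete probability
#' distribution over its active nodes, x_p = x / sum(x). (The scalar
#' iteration weight cancels in the normalization and is kept separately
#' for the final fusion.)
#'
#' @param x nonnegative solution on the active set.
#' @return vector summing to 1, or `NULL` if the solution is all zero
#'   (degenerate iteration, skipped from the ROI update).
#' @export
probabilistic_distribution <- function(x) {
  x <- pmax(x, 0)
  s <- sum(x)
  if (s == 0) return(NULL)
  x / s
}

#' Probability-weighted ROI centre
#'
#' @param coords n x 3 coordinates of the active nodes.
#' @param x_p probability distribution over those nodes (sums to 1).
#' @return length-3 centre (mm).
#' @export
roi_center <- function(coords, x_p) {
  as.numeric(crossprod(coords, x_p))
}

#' Probability-weighted covariance of the active nodes
#'
#' Per-axis variances and cross-covariances of the node coordinates
#' under the distribution x_p, each multiplied by N/(N-1) (N = number of
#' active nodes) as an unbiasedness correction.
#'
#' @param coords n x 3 coordinates.
#' @param x_p probability distribution over the nodes.
#' @param center precomputed [roi_center()]; recomputed if missing.
#' @return symmetric positive semidefinite 3 x 3 matrix.
#' @export
roi_covariance <- function(coords, x_p, center = NULL) {
  n <- nrow(coords)
  if (is.null(center)) center <- roi_center(coords, x_p)
  if (n < 2L) return(matrix(0, 3, 3))
  d <- sweep(coords, 2L, center)
  m <- crossprod(d, d * x_p) * n / (n - 1)
  (m + t(m)) / 2
}

#' Covariance-eigenframe ROI box
#'
#' Eigendecomposes the weighted covariance; the eigenvectors form the
#' box frame and the half-length along axis k is |eigenvalue_k| * size,
#' floored at `floor` so a degenerate covariance never empties the
#' region.
#'
#' @param m_cov symmetric 3 x 3 covariance.
#' @param center box centre (mm).
#' @param size scale factor, one of 0.5, 1, 2.
#' @param floor minimum half-length (mm), typically the mesh spacing.
#' @return object of class `roi_box`: `center`, `axes` (columns =
#'   orthonormal eigenvectors), `half_lengths`.
#' @export
roi_box <- function(m_cov, center, size = 1, floor = 1) {
  if (max(abs(m_cov - t(m_cov))) > 1e-8 * max(1, max(abs(m_cov))))
    stop("covariance matrix must be symmetric")
  eg <- eigen((m_cov + t(m_cov)) / 2, symmetric = TRUE)
  structure(list(center = as.numeric(center), axes = eg$vectors,
                 half_lengths = pmax(abs(eg$values) * size, floor)),
            class = "roi_box")
}

#' Nodes inside an ROI box
#'
#' Tests each node's coordinates in the box eigenframe against the
#' per-axis half-lengths and returns the contained nodes sorted by
#' ascending Euclidean distance to the box centre (ties broken by node
#' index).
#'
#' @param nodes n x 3 coordinate matrix.
#' @param box a [roi_box()].
#' @return integer indices into `nodes` (possibly empty).
#' @export
nodes_in_box <- function(nodes, box) {
  d <- sweep(nodes, 2L, box$center)
  local <- d %*% box$axes
  inside <- abs(local[, 1L]) <= box$half_lengths[1L] &
            abs(local[, 2L]) <= box$half_lengths[2L] &
            abs(local[, 3L]) <= box$half_lengths[3L]
  idx <- which(unname(inside))
  if (length(idx) == 0L) return(integer(0))
  dist <- sqrt(rowSums(d[idx, , drop = FALSE]^2))
  idx[order(dist, idx)]
}

#' Attenuation coefficient of the node-budget schedule
#'
#' beta = (cut_num / num_f)^(1/(l_max - 1)): the per-iteration shrink
#' factor that takes the initial budget down to `num_f` nodes (one
#' tetrahedron by default) over `l_max` iterations. If the budget is
#' already at or below `num_f`, beta = 1 (no shrink).
#'
#' @param cut_num current retained-node budget.
#' @param num_f target number of nodes at the final iteration.
#' @param l_max maximum number of iterations.
#' @return beta >= 1.
#' @export
attenuation_coefficient <- function(cut_num, num_f = 4L, l_max = 50L) {
  if (num_f < 1L || l_max < 2L) stop("need num_f >= 1 and l_max >= 2")
  if (cut_num < num_f) return(1)
  (cut_num / num_f)^(1 / (l_max - 1))
}

#' Update the ROI scale factor
#'
#' Compares the ROI node supply to the two-step-ahead budget:
#' q = roi_count / (cut_num / beta^2). If q > 2 the next box is doubled
#' (size 2); if q < 1 it is halved (size 0.5); otherwise size 1.
#'
#' @param roi_count number of nodes the current ROI captured.
#' @param cut_num current budget.
#' @param beta attenuation coefficient (>= 1).
#' @return one of 2, 1, 0.5.
#' @export
update_size <- function(roi_count, cut_num, beta) {
  q <- roi_count / (cut_num / beta^2)
  if (q > 2) 2 else if (q < 1) 0.5 else 1
}

#' Refresh the active index set
#'
#' Shrinks the budget to ceil(cut_num / beta), ranks the current active
#' nodes by descending intensity (ties by index) and keeps the top
#' new-budget of them as `index_sp_descend`, concatenates the ROI nodes
#' first and the ranked nodes after, removes duplicates keeping first
#' occurrence (ROI nodes take precedence), and truncates to the new
#' budget.
#'
#' @param x intensities on `index_sp`.
#' @param index_sp current active node indices.
#' @param index_sp_roi ROI node indices (distance-sorted); may be empty,
#'   in which case only the ranked nodes survive.
#' @param cut_num current budget.
#' @param beta attenuation coefficient.
#' @return list with `index_sp` (new active set) and `cut_num`.
#' @export
refresh_index <- function(x, index_sp, index_sp_roi, cut_num, beta) {
  new_cut <- as.integer(ceiling(cut_num / beta))
  ord <- order(-x, index_sp)
  descend <- index_sp[ord][seq_len(min(new_cut, length(index_sp)))]
  merged <- c(index_sp_roi, descend)
  merged <- merged[!duplicated(merged)]
  list(index_sp = merged[seq_len(min(new_cut, length(merged)))],
       cut_num = new_cut)
}

#' Gaussian filtering of the iteration history
#'
#' Retains the iterations whose residual and cosine similarity both lie
#' within one standard deviation of their respective means (boundaries
#' inclusive). If the intersection is empty, the single highest-weight
#' iteration is retained instead.
#'
#' @param e_l2 residuals per iteration.
#' @param e_cos cosine similarities per iteration.
#' @return integer indices of the retained iterations.
#' @export
gaussian_filter_iterations <- function(e_l2, e_cos) {
  n <- length(e_l2)
  if (n == 1L) return(1L)
  within_band <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s)) s <- 0
    abs(v - mean(v)) <= s + 1e-12 * max(abs(v), 1)
  }
  keep <- which(within_band(e_l2) & within_band(e_cos))
  if (length(keep) == 0L)
    keep <- which.max(probability_weights(e_l2, e_cos))
  keep
}

#' Fuse retained iterations into the final distribution
#'
#' Recomputes the probability weights over the retained iterations only,
#' embeds each retained solution into the global node vector (zeros off
#' its active set) and forms the weighted sum of the raw solutions; the
#' total is then normalized once to unit mass. Summing raw amplitudes
#' matters: late compact iterations carry much larger nodal intensities
#' than early diffuse ones, so the fusion concentrates where the loop
#' converged. The result is still a convex combination of the
#' individually normalized embeddings (with coefficients proportional
#' to weight times iteration mass), hence nonnegative with total mass
#' 1.
#'
#' @param records list of iteration records, each with `index_sp`, `x`
#'   (clamped), `e_l2`, `e_cos`.
#' @param retained indices into `records`.
#' @param n_nodes length of the global node vector.
#' @return list with `x_final` (length `n_nodes`) and `weights` (over
#'   the retained iterations).
#' @export
final_distribution <- function(records, retained, n_nodes) {
  if (length(retained) == 0L) stop("retained must be nonempty")
  recs <- records[retained]
  usable <- vapply(recs, function(r) sum(pmax(r$x, 0)) > 0, logical(1))
  if (!any(usable)) stop("all retained iterations are degenerate (zero mass)")
  recs <- recs[usable]
  retained <- retained[usable]
  w <- probability_weights(vapply(recs, `[[`, 0, "e_l2"),
                           vapply(recs, `[[`, 0, "e_cos"))
  x_final <- numeric(n_nodes)
  for (i in seq_along(recs)) {
    xi <- pmax(recs[[i]]$x, 0)
    x_final[recs[[i]]$index_sp] <- x_final[recs[[i]]$index_sp] + w[i] * xi
  }
  x_final <- x_final / sum(x_final)
  list(x_final = x_final, weights = w, retained = retained)
}

#' Run the P-EDDRS reconstruction loop
#'
#' Executes the full framework: an initial global one-step solve, then
#' repeated cycles of (clamp, evaluate residual and cosine similarity,
#' refresh the probability weights over the whole history, normalize to
#' a probabilistic distribution, build the covariance-eigenframe ROI
#' box, rescale, and refresh the active index set against the
#' attenuation-scheduled budget), until a single node remains or
#' `l_max` iterations have run; finally the history is Gaussian-filtered
#' and fused into the global source distribution.
#'
#' The attenuation coefficient is computed once from the initial
#' candidate count, so the budget follows the analytic schedule
#' c0, ceil(c0/beta), ceil(ceil(c0/beta)/beta), ... down to `num_f`
#' at `l_max`. When the solver's regularization weight is left at its
#' default, each iteration applies the scale-free default of the
#' subsystem it actually solves (1e-3 times its squared spectral norm),
#' so shrinking the active set does not over-regularize the solve.
#'
#' @param sysmat a [build_system_matrix()] result, or a plain M x N
#'   matrix (then `coords` must give the candidate coordinates).
#' @param B measurement vector (length M).
#' @param mesh the [tet_mesh()] the candidates live on (used for node
#'   coordinates and the ROI half-length floor); optional if `coords`
#'   is given.
#' @param solver a [solver_spec()].
#' @param l_max maximum number of iterations (default 50).
#' @param num_f target node count of the final iteration (default 4, a
#'   tetrahedron).
#' @param coords optional N x 3 candidate coordinates overriding
#'   `mesh`.
#' @param floor ROI half-length floor (mm); default the mesh spacing.
#' @return object of class `recon_result`: `x_final` over all mesh
#'   nodes (sums to 1), `records`, `retained`, `weights`, `audit`
#'   data frame, `col_nodes`.
#' @export
run_peddrs <- function(sysmat, B, mesh = NULL, solver = solver_spec("tikhonov"),
                       l_max = 50L, num_f = 4L, coords = NULL, floor = NULL) {
  if (inherits(sysmat, "system_matrix")) {
    A <- sysmat$A
    col_nodes <- sysmat$col_nodes
  } else {
    A <- as.matrix(sysmat)
    col_nodes <- seq_len(ncol(A))
  }
  if (is.null(coords)) {
    if (is.null(mesh)) stop("either mesh or coords must be supplied")
    coords <- mesh$nodes[col_nodes, , drop = FALSE]
  }
  n_nodes <- if (is.null(mesh)) max(col_nodes) else nrow(mesh$nodes)
  if (is.null(floor))
    floor <- if (is.null(mesh)) 1 else mesh$spacing

  N <- ncol(A)
  index_sp <- seq_len(N)           # positions into col_nodes
  cut_num <- N
  beta <- attenuation_coefficient(cut_num, num_f, l_max)
  size <- 1
  records <- list()
  audit <- list()
  i <- 0L
  repeat {
    i <- i + 1L
    x <- tryCatch(solve_one_step(solver, A[, index_sp, drop = FALSE], B),
                  error = function(e) e)
    if (inherits(x, "error")) {
      if (i == 1L) stop("solver failed on the initial global solve: ",
                        conditionMessage(x))
      warning(sprintf("iteration %d solver failure skipped: %s", i,
                      conditionMessage(x)))
      break
    }
    x <- pmax(as.numeric(x), 0)
    e_l2 <- evaluate_l2(A, index_sp, x, B)
    e_cos <- evaluate_cos(A, index_sp, x, B)
    records[[i]] <- list(index_sp = index_sp, x = x,
                         e_l2 = e_l2, e_cos = e_cos)
    w_all <- probability_weights(vapply(records, `[[`, 0, "e_l2"),
                                 vapply(records, `[[`, 0, "e_cos"))
    for (j in seq_along(records)) records[[j]]$weight <- w_all[j]

    x_p <- probabilistic_distribution(x)
    if (is.null(x_p)) {
      roi_pos <- integer(0)   # degenerate iteration: energy ranking only
    } else {
      ctr <- roi_center(coords[index_sp, , drop = FALSE], x_p)
      mcov <- roi_covariance(coords[index_sp, , drop = FALSE], x_p, ctr)
      box <- roi_box(mcov, ctr, size = size, floor = floor)
      roi_pos <- nodes_in_box(coords, box)   # may reclaim dropped nodes
    }
    size <- update_size(length(roi_pos), cut_num, beta)
    audit[[i]] <- data.frame(iteration = i, n_active = length(index_sp),
                             e_l2 = e_l2, e_cos = e_cos,
                             weight = w_all[i], size = size,
                             cut_num = cut_num)
    rf <- refresh_index(x, index_sp, roi_pos, cut_num, beta)
    if (length(rf$index_sp) <= 1L || i >= l_max) break
    index_sp <- rf$index_sp
    cut_num <- rf$cut_num
  }

  e_l2s <- vapply(records, `[[`, 0, "e_l2")
  e_coss <- vapply(records, `[[`, 0, "e_cos")
  retained <- gaussian_filter_iterations(e_l2s, e_coss)
  # Records carry positions into col_nodes; remap for global embedding.
  recs_global <- lapply(records, function(r) {
    r$index_sp <- col_nodes[r$index_sp]; r
  })
  fused <- final_distribution(recs_global, retained, n_nodes)
  structure(
    list(x_final = fused$x_final, records = recs_global,
         retained = fused$retained, weights = fused$weights,
         audit = do.call(rbind, audit), col_nodes = col_nodes,
         solver = solver, beta = beta, l_max = l_max, num_f = num_f),
    class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf(
    "recon_result: %s, %d iterations (%d retained), beta = %.4f\n",
    x$solver$method, nrow(x$audit), length(x$retained), x$beta))
  cat(sprintf("  final residual e_l2 = %.4g, e_cos = %.4f\n",
              x$audit$e_l2[nrow(x$audit)], x$audit$e_cos[nrow(x$audit)]))
  invisible(x)
}
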