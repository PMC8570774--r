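#' One-step inverse solver specification
#'
#' @param method one of `"tikhonov"`, `"dsvd"`, `"lassolsqr"`, `"omp"`.
#' @param lambda regularization weight; `NULL` selects the scale-free
#'   default 1e-3 * sigma_max(A)^2 at solve time.
#' @param k OMP sparsity level (number of greedy steps).
#' @param iters inner iteration cap for the soft-thresholded solver.
#' @return object of class `solver_spec`.
#' @export
solver_spec <- function(method = c("tikhonov", "dsvd", "lassolsqr", "omp"),
                        lambda = NULL, k = 10L, iters = 500L) {
  method <- match.arg(method)
  if (!is.null(lambda) && (!is.finite(lambda) || lambda < 0))
    stop("lambda must be >= 0")
  if (k < 1L) stop("k must be >= 1")
  structure(list(method = method, lambda = lambda, k = as.integer(k),
                 iters = as.integer(iters)),
            class = "solver_spec")
}

# Largest singular value by power iteration on A'A; deterministic
# (fixed start vector), accurate to ~1e-8 relative which is ample for
# default-regularization and step-size purposes.
spectral_norm <- function(A, tol = 1e-9, maxit = 200L) {
  n <- ncol(A)
  v <- rep(1 / sqrt(n), n)
  s_old <- 0
  for (it in seq_len(maxit)) {
    w <- as.numeric(crossprod(A, A %*% v))
    s <- sqrt(sum(w * v))
    nv <- sqrt(sum(w^2))
    if (nv == 0) return(0)
    v <- w / nv
    if (abs(s - s_old) <= tol * max(s, 1e-300)) break
    s_old <- s
  }
  s
}

default_lambda <- function(A) 1e-3 * spectral_norm(A)^2

#' Tikhonov (L2) regularized solution
#'
#' x = argmin ||Ax - B||^2 + lambda ||x||^2, solved through the normal
#' equations (A'A + lambda I) x = A'B, or the equivalent dual form
#' x = A'(AA' + lambda I)^{-1} B when A has fewer rows than columns.
#'
#' @param A M x N matrix. @param B length-M measurement vector.
#' @param lambda regularization weight > 0 (`NULL`: scale-free default).
#' @return length-N solution vector.
#' @export
solve_tikhonov <- function(A, B, lambda = NULL) {
  A <- as.matrix(A)
  if (is.null(lambda)) lambda <- default_lambda(A)
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (nrow(A) < ncol(A)) {
    G <- tcrossprod(A)
    diag(G) <- diag(G) + lambda
    as.numeric(crossprod(A, solve(G, B)))
  } else {
    G <- crossprod(A)
    diag(G) <- diag(G) + lambda
    as.numeric(solve(G, crossprod(A, B)))
  }
}

#' Damped SVD solution
#'
#' Over the thin SVD A = U diag(sigma) V', applies the damped filter
#' factors sigma_i/(sigma_i + lambda):
#' x = sum_i [sigma_i/(sigma_i+lambda)] (u_i'B / sigma_i) v_i.
#' Singular values below 1e-12 * sigma_max are treated as zero.
#'
#' @inheritParams solve_tikhonov
#' @return length-N solution vector.
#' @export
solve_dsvd <- function(A, B, lambda = NULL) {
  A <- as.matrix(A)
  if (all(A == 0)) {
    warning("zero system matrix; returning x = 0")
    return(numeric(ncol(A)))
  }
  if (is.null(lambda)) lambda <- default_lambda(A)
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  sv <- svd(A)
  keep <- sv$d > 1e-12 * sv$d[1L]
  coef <- (crossprod(sv$u[, keep, drop = FALSE], B)) /
    (sv$d[keep] + lambda)
  as.numeric(sv$v[, keep, drop = FALSE] %*% coef)
}

#' Soft-thresholded LSQR-type L1 solution
#'
#' Approximately minimizes ||Ax - B||^2 + lambda ||x||_1 by proximal
#' gradient steps (least-squares gradient step followed by
#' soft-thresholding) with the fixed step 1/(2 sigma_max^2). With
#' lambda = 0 the problem is plain least squares and the minimum-norm
#' solution is returned directly.
#'
#' @inheritParams solve_tikhonov
#' @param iters maximum number of proximal steps.
#' @param tol relative step-change convergence tolerance.
#' @return length-N solution with attribute `converged`.
#' @export
solve_lassolsqr <- function(A, B, lambda = NULL, iters = 500L, tol = 1e-10) {
  A <- as.matrix(A)
  if (is.null(lambda)) lambda <- default_lambda(A)
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be >= 0")
  if (lambda == 0) {
    sv <- svd(A)
    keep <- sv$d > 1e-12 * max(sv$d, 0)
    x <- as.numeric(sv$v[, keep, drop = FALSE] %*%
                      (crossprod(sv$u[, keep, drop = FALSE], B) / sv$d[keep]))
    attr(x, "converged") <- TRUE
    return(x)
  }
  L <- 2 * spectral_norm(A)^2
  if (L == 0) {
    x <- numeric(ncol(A)); attr(x, "converged") <- TRUE
    return(x)
  }
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  x <- numeric(ncol(A))
  converged <- FALSE
  for (it in seq_len(iters)) {
    grad <- 2 * as.numeric(crossprod(A, A %*% x - B))
    x_new <- soft(x - grad / L, lambda / L)
    if (sqrt(sum((x_new - x)^2)) <= tol * max(1, sqrt(sum(x^2)))) {
      x <- x_new; converged <- TRUE; break
    }
    x <- x_new
  }
  if (!converged)
    attr(x, "converged") <- FALSE
  else
    attr(x, "converged") <- TRUE
  x
}

#' Orthogonal matching pursuit
#'
#' Greedy support selection: at each step the column with maximal
#' absolute correlation between its l2-normalized direction and the
#' current residual joins the support, the solution is least-squares
#' refit on the support, and the residual is updated; stops after `k`
#' steps or when the residual drops below `tol`. Ties break toward the
#' lowest column index; rank-deficient refits use the minimum-norm
#' least-squares solution.
#'
#' @inheritParams solve_tikhonov
#' @param k sparsity level (number of greedy steps), 1 <= k <= N.
#' @param tol absolute residual-norm stopping tolerance; `NULL` gives
#'   1e-6 * ||B||.
#' @return length-N solution vector, zero off the selected support.
#' @export
solve_omp <- function(A, B, k = 10L, tol = NULL) {
  A <- as.matrix(A)
  N <- ncol(A)
  if (k < 1L || k > N) stop("k must satisfy 1 <= k <= ncol(A)")
  if (is.null(tol)) tol <- 1e-6 * sqrt(sum(B^2))
  nrm <- sqrt(colSums(A^2))
  nrm[nrm == 0] <- Inf   # dead columns are never selected
  support <- integer(0)
  r <- as.numeric(B)
  x <- numeric(N)
  for (step in seq_len(k)) {
    corr <- abs(as.numeric(crossprod(A, r))) / nrm
    corr[support] <- -Inf
    j <- which.max(corr)   # which.max returns the first maximum
    support <- c(support, j)
    As <- A[, support, drop = FALSE]
    xs <- min_norm_lstsq(As, B)
    r <- as.numeric(B - As %*% xs)
    if (sqrt(sum(r^2)) < tol) break
  }
  x[support] <- xs
  x
}

# Minimum-norm least squares via thin SVD (robust to rank deficiency).
min_norm_lstsq <- function(A, B) {
  sv <- svd(A)
  keep <- sv$d > 1e-12 * max(sv$d, 0)
  if (!any(keep)) return(numeric(ncol(A)))
  as.numeric(sv$v[, keep, drop = FALSE] %*%
               (crossprod(sv$u[, keep, drop = FALSE], B) / sv$d[keep]))
}

#' Dispatch a one-step solve
#'
#' @param spec a [solver_spec()].
#' @param A system matrix. @param B measurements.
#' @return solution vector from the selected method.
#' @export
solve_one_step <- function(spec, A, B) {
  switch(spec$method,
    tikhonov  = solve_tikhonov(A, B, spec$lambda),
    dsvd      = solve_dsvd(A, B, spec$lambda),
    lassolsqr = solve_lassolsqr(A, B, spec$lambda, spec$iters),
    omp       = solve_omp(A, B, spec$k))
}
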