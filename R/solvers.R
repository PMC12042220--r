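#' Sparse linear least squares by preconditioned CGLS
#'
#' Minimizes \eqn{\|Ax - b\|_2} for a sparse `A` using conjugate gradients
#' on the normal equations (CGLS), with Jacobi (column-norm) scaling as a
#' diagonal preconditioner. All large systems in the pipeline — the
#' log-shading decomposition, the per-pixel normal solve and the height
#' integration — go through this routine, which keeps every matrix sparse
#' so the systems fit in memory at photographic resolutions.
#'
#' Convergence is declared when the normal-equation residual satisfies
#' \eqn{\|A^T(b - Ax)\| \le tol \cdot \|A^T b\|}. Non-convergence within
#' `max_iter` iterations raises a condition of class
#' `pictodepth_convergence_error` carrying the final relative residual.
#'
#' @param A sparse matrix (`dgCMatrix` or coercible), m x n with m >= n rows.
#' @param b numeric right-hand side of length m.
#' @param tol relative tolerance on the normal-equation residual.
#' @param max_iter iteration cap.
#' @param method `"cgls"` (default) or `"direct"`, the latter solving the
#'   normal equations by sparse Cholesky (used as an internal cross-check).
#' @return list with `x` (solution), `iterations`, `relative_residual`
#'   (normal-equation scale) and `residual_norm` (\eqn{\|b - Ax\|_2}).
#' @export
lsq_solve <- function(A, b, tol = 1e-8, max_iter = 10000L,
                      method = c("cgls", "direct")) {
  method <- match.arg(method)
  A <- methods::as(A, "CsparseMatrix")
  b <- as.numeric(b)
  abort_if(nrow(A) != length(b), "lsq_solve: nrow(A) != length(b)")
  abort_if(!is_scalar_num(tol) || tol <= 0, "lsq_solve: tol must be > 0")

  if (method == "direct") {
    AtA <- Matrix::crossprod(A)
    Atb <- as.numeric(Matrix::crossprod(A, b))
    x <- as.numeric(Matrix::solve(AtA, Atb))
    r <- b - as.numeric(A %*% x)
    nr <- as.numeric(sqrt(sum(as.numeric(Matrix::crossprod(A, r))^2)))
    return(list(x = x, iterations = 0L,
                relative_residual = nr / max(sqrt(sum(Atb^2)), .Machine$double.eps),
                residual_norm = sqrt(sum(r^2))))
  }

  # Jacobi column scaling: solve for y with A D y = b, x = D y
  cn <- sqrt(Matrix::colSums(A^2))
  cn[cn == 0] <- 1
  D <- Matrix::Diagonal(x = 1 / cn)
  As <- A %*% D

  At_b <- as.numeric(Matrix::crossprod(As, b))
  nrm0 <- sqrt(sum(At_b^2))
  n <- ncol(A)
  y <- numeric(n)
  r <- b                          # b - As y
  s <- At_b                       # As^T r
  p <- s
  gamma <- sum(s^2)
  it <- 0L
  rel <- 1
  if (nrm0 == 0) {
    return(list(x = numeric(n), iterations = 0L, relative_residual = 0,
                residual_norm = sqrt(sum(b^2))))
  }
  while (it < max_iter) {
    q <- as.numeric(As %*% p)
    denom <- sum(q^2)
    if (denom == 0) break
    alpha <- gamma / denom
    y <- y + alpha * p
    r <- r - alpha * q
    s <- as.numeric(Matrix::crossprod(As, r))
    gamma_new <- sum(s^2)
    it <- it + 1L
    rel <- sqrt(gamma_new) / nrm0
    if (rel <= tol) break
    p <- s + (gamma_new / gamma) * p
    gamma <- gamma_new
  }
  if (rel > tol) {
    cond <- structure(
      class = c("pictodepth_convergence_error", "pictodepth_error",
                "error", "condition"),
      list(message = sprintf(
        "least-squares solver did not reach tol %.3g in %d iterations (relative residual %.3g)",
        tol, it, rel), call = sys.call(-1),
        relative_residual = rel, iterations = it))
    stop(cond)
  }
  x <- as.numeric(D %*% y)
  list(x = x, iterations = it, relative_residual = rel,
       residual_norm = sqrt(sum(r^2)))
}

# Builds a sparse matrix from row/col/value triplets accumulated in lists.
triplet_matrix <- function(i, j, x, nrow, ncol) {
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nrow, ncol))
}
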