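#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Minimizes `||A x - b||^2` subject to `x >= 0`.  This is the estimator at
#' the heart of the supervised clustering step: every voxel's normalized
#' time-activity curve is decomposed as a non-negative combination of the
#' kinetic class curves.  Implemented as the classical active-set algorithm
#' of Lawson & Hanson; the problem sizes here (tens of frames, a handful of
#' classes) converge in a few passes and the solution is deterministic for
#' a fixed input.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector, length m.
#' @param tol dual-feasibility tolerance, relative to the scale of `A'b`.
#' @return list with `x` (coefficients, all >= 0), `residual_ss` (sum of
#'   squared residuals) and `iterations` (outer-loop count).
#' @export
nnls <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  m <- nrow(A); n <- ncol(A)
  if (length(b) != m) stop("dim mismatch: nrow(A) = ", m,
                           ", length(b) = ", length(b))
  if (!all(is.finite(A)) || !all(is.finite(b)))
    stop("non-finite values in the NNLS problem")
  x <- numeric(n)
  passive <- logical(n)
  scale <- max(abs(crossprod(A, b)), 1)
  eps <- tol * scale
  outer <- 0L
  maxouter <- 10L * n + 50L
  ls_on <- function(P) {
    z <- numeric(n)
    cf <- qr.coef(qr(A[, P, drop = FALSE]), b)
    cf[is.na(cf)] <- 0                        # rank deficiency: drop to 0
    z[P] <- cf
    z
  }
  while (outer < maxouter) {
    outer <- outer + 1L
    w <- drop(crossprod(A, b - A %*% x))
    free <- which(!passive)
    if (!length(free) || max(w[free]) <= eps) break
    passive[free[which.max(w[free])]] <- TRUE
    repeat {
      P <- which(passive)
      z <- ls_on(P)
      if (all(z[P] > 0)) { x <- z; break }
      neg <- P[z[P] <= 0]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      if (!is.finite(alpha)) alpha <- 0
      x <- x + alpha * (z - x)
      drop_idx <- P[x[P] <= max(.Machine$double.eps * scale, 1e-14)]
      if (!length(drop_idx)) drop_idx <- P[which.min(x[P])]
      passive[drop_idx] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) break
    }
  }
  x[x < 0] <- 0
  r <- b - A %*% x
  list(x = as.numeric(x), residual_ss = sum(r^2), iterations = outer)
}
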