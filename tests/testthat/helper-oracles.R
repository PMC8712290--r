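# Independent oracles used across the suite.

# Exact minimum of ||A w - b||^2 over the product grid {0, step, ..., box}^n.
# For each grid point of w[2..n] the 1-D problem in w[1] is a convex
# quadratic, so its grid minimizer is one of the two grid neighbours of the
# continuous minimizer (clamped to the box).  This computes the same value
# as brute-force enumeration of the full grid without materializing it.
grid_nnls_min <- function(A, b, step = 0.01, box = 3) {
  G <- crossprod(A)
  h <- drop(crossprod(A, b))
  c0 <- sum(b^2)
  n <- ncol(A)
  grid <- seq(0, box, by = step)
  if (n == 1L) {
    return(min(G[1, 1] * grid^2 - 2 * h[1] * grid + c0))
  }
  rest <- as.matrix(expand.grid(rep(list(grid), n - 1L)))
  lin <- drop(rest %*% G[1, -1]) - h[1]
  quad <- rowSums((rest %*% G[-1, -1, drop = FALSE]) * rest) -
    2 * drop(rest %*% h[-1]) + c0
  wstar <- -lin / G[1, 1]
  lo <- pmin(pmax(floor(wstar / step) * step, 0), box)
  hi <- pmin(lo + step, box)
  f <- function(w1) G[1, 1] * w1^2 + 2 * w1 * lin + quad
  min(pmin(f(lo), f(hi)))
}

# Fine-grid numerical version of the compartment-model frame averaging:
# gamma-variate input, 1TCM impulse response, trapezoid convolution on a
# dt-grid, then frame averaging.
numeric_templates <- function(schedule, profile, dt = 0.1) {
  lam <- 1 / profile$blood_beta
  A <- profile$blood_peak / (profile$blood_beta * exp(-1))
  tmax <- max(schedule$end)
  tt <- seq(0, tmax, by = dt)
  cp <- A * tt * exp(-lam * tt)
  out <- matrix(NA_real_, schedule$n_frames, 5L,
                dimnames = list(NULL, c("lbgm", "wm", "blood", "hbgm",
                                        "csf")))
  frame_avg <- function(v) {
    vapply(seq_len(schedule$n_frames), function(j) {
      sel <- which(tt >= schedule$start[j] & tt <= schedule$end[j])
      x <- v[sel]
      n <- length(x)
      (sum(x) - (x[1] + x[n]) / 2) / (n - 1)   # trapezoid mean
    }, numeric(1))
  }
  out[, "blood"] <- frame_avg(cp)
  for (cls in c("lbgm", "wm", "hbgm", "csf")) {
    k1 <- profile$K1[[cls]] / 60
    k2 <- profile$k2[[cls]] / 60
    irf <- k1 * exp(-k2 * tt)
    conv <- stats::convolve(cp, rev(irf), type = "open")[seq_along(tt)] * dt
    # trapezoid end-correction (cp(0) = 0, so only the t-end term remains)
    conv <- conv - 0.5 * dt * cp * irf[1]
    out[, cls] <- frame_avg(conv)
  }
  out
}

# per-frame mean over a set of linear voxel indices, straight from the array
brute_mask_mean <- function(vol4d, idx) {
  d <- dim(vol4d)
  vapply(seq_len(d[4]), function(j) {
    fr <- vol4d[, , , j]
    mean(fr[idx])
  }, numeric(1))
}
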