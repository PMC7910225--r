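# Internal numeric helpers shared across modules.

# DFT sample frequencies in cycles per unit (like numpy's fftfreq).
fftfreq <- function(n, d = 1) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}

# 2-D FFT / inverse of a real matrix.
fft2 <- function(x) stats::fft(x)
ifft2 <- function(X) Re(stats::fft(X, inverse = TRUE)) / length(X)

# Reflective padding of a matrix by (py, px) on each side.
padReflect <- function(x, py, px) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(rev(seq_len(min(py, nr))), seq_len(nr),
          nr + 1 - seq_len(min(py, nr)))
  if (py > nr) ri <- rep(ri, length.out = nr + 2 * py) # degenerate tiny frames
  ci <- c(rev(seq_len(min(px, nc))), seq_len(nc),
          nc + 1 - seq_len(min(px, nc)))
  if (px > nc) ci <- rep(ci, length.out = nc + 2 * px)
  x[ri, ci, drop = FALSE]
}

cropPad <- function(x, py, px, nr, nc) {
  x[py + seq_len(nr), px + seq_len(nc), drop = FALSE]
}

# 1-D Gaussian kernel, normalised.
gaussKernel <- function(sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) return(1)
  k <- exp(-0.5 * (seq(-radius, radius) / sigma)^2)
  k / sum(k)
}

# Separable Gaussian smoothing of a matrix (reflective boundaries) via a
# banded convolution matrix; cheap at the slice sizes used here.
gaussSmooth2d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussKernel(sigma)
  r <- (length(k) - 1) / 2
  smooth1 <- function(m) {
    n <- nrow(m)
    idx <- outer(seq_len(n), seq(-r, r), "+")
    idx[idx < 1] <- 1 - idx[idx < 1]          # reflect
    idx[idx > n] <- 2 * n - idx[idx > n]
    idx[idx < 1] <- 1; idx[idx > n] <- n
    K <- matrix(0, n, n)
    for (j in seq_along(k)) {
      K[cbind(seq_len(n), idx[, j])] <- K[cbind(seq_len(n), idx[, j])] + k[j]
    }
    K %*% m
  }
  t(smooth1(t(smooth1(x))))
}

# Separable Gaussian smoothing of a 3-D array along every axis.
gaussSmooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  k <- gaussKernel(sigma)
  r <- (length(k) - 1) / 2
  convAlong <- function(a, axis) {
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(a, perm), nrow = d[axis])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      idx <- seq_len(n) + (j - 1 - r)
      idx[idx < 1] <- 1 - idx[idx < 1]
      idx[idx > n] <- 2 * n - idx[idx > n]
      idx[idx < 1] <- 1; idx[idx > n] <- n
      out <- out + k[j] * m[idx, , drop = FALSE]
    }
    aperm(array(out, d[perm]), order(perm))
  }
  for (ax in 1:3) a <- convAlong(a, ax)
  a
}

# Trilinear sampling at 1-based fractional coordinates; out-of-grid -> fill.
sampleVolume <- function(vol, xs, ys, zs, fill = 0) {
  v <- sample_trilinear_cpp(vol, as.numeric(xs) - 1, as.numeric(ys) - 1,
                            as.numeric(zs) - 1, fill)
  v
}

# Linear interpolation into a vector at fractional 1-based positions.
interp1 <- function(y, pos, fill = 0) {
  n <- length(y)
  out <- rep(fill, length(pos))
  ok <- pos >= 1 & pos <= n
  p <- pos[ok]
  i0 <- pmin(floor(p), n - 1)
  f <- p - i0
  out[ok] <- y[i0] * (1 - f) + y[i0 + 1] * f
  out
}

# Deterministic child seeds derived from one master seed (kept < 2^31).
childSeed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
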