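#' Static flat-field correction
#'
#' \code{(raw - meanDark) / (meanFlat - meanDark)}: the conventional
#' normalization of a projection by the mean calibration frames.
#'
#' @param rawFrame raw detector frame (matrix).
#' @param model a \linkS4class{FlatFieldModel}.
#' @return normalized (transmission) frame.
#' @export
correctStatic <- function(rawFrame, model) {
  denom <- model@flatMean - model@darkMean
  nbad <- sum(denom <= 0)
  if (nbad > 0)
    stop(sprintf("%d pixels with non-positive flat-dark difference", nbad))
  (rawFrame - model@darkMean) / denom
}

#' Fit a principal-component flat-field basis
#'
#' Eigen-decomposition of the pixel covariance of the dark-subtracted
#' flat-field stack, computed through the frame-space Gram matrix.  The
#' leading K eigenvectors ("eigen-flats") span the illumination drift;
#' directions with (numerically) zero variance are completed with
#' deterministic orthonormal fillers so the basis always has K columns.
#'
#' @param flatStack raw flats, array (n_flat x rows x cols).
#' @param darkMean mean dark frame.
#' @param K number of eigen-flats to keep; must be <= n_flat - 1.
#' @return A \linkS4class{FlatFieldModel}.
#' @export
fitFlatBasis <- function(flatStack, darkMean, K = 5) {
  n <- dim(flatStack)[1]
  if (K > n - 1) stop("K must be at most n_flat - 1")
  nr <- dim(flatStack)[2]; nc <- dim(flatStack)[3]
  X <- matrix(flatStack, n)                # frames in rows
  mu <- colMeans(X)
  Cm <- sweep(X, 2, mu)
  G <- tcrossprod(Cm) / n                  # frame-space Gram
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  U <- matrix(0, nr * nc, K)
  evK <- numeric(K)
  tol <- max(ev[1], 0) * 1e-10 + 1e-30
  kgood <- 0L
  for (k in seq_len(K)) {
    if (ev[k] > tol) {
      u <- crossprod(Cm, eg$vectors[, k])
      U[, k] <- u / sqrt(sum(u^2))
      evK[k] <- ev[k]
      kgood <- k
    }
  }
  if (kgood < K) {
    # deterministic fillers orthogonal to the informative components
    basis <- U[, seq_len(kgood), drop = FALSE]
    j <- 1L
    for (k in seq(kgood + 1L, K)) {
      repeat {
        e <- numeric(nr * nc); e[j] <- 1; j <- j + 1L
        if (ncol(basis) > 0) e <- e - basis %*% crossprod(basis, e)
        if (sqrt(sum(e^2)) > 0.5) break
      }
      e <- e / sqrt(sum(e^2))
      U[, k] <- e
      basis <- cbind(basis, e)
    }
  }
  new("FlatFieldModel", darkMean = darkMean,
      flatMean = matrix(mu, nr, nc) + darkMean,
      eigenflats = array(U, c(nr, nc, K)), eigenvalues = evK)
}

#' Dynamic (principal-component) flat-field correction
#'
#' Estimates per-frame drift coefficients by least squares on a sample-free
#' background region (default: the 20 outermost detector columns on each
#' side) and divides the dark-subtracted frame by the per-frame effective
#' flat \code{(flatMean - darkMean) + sum_k w_k u_k}.
#'
#' @param rawFrame raw detector frame.
#' @param model a \linkS4class{FlatFieldModel}.
#' @param backgroundRegion logical matrix (same shape) marking sample-free
#'   pixels, or NULL for the default margin columns.
#' @param marginCols margin width used when \code{backgroundRegion} is NULL.
#' @return list with \code{frame} (corrected) and \code{weights}.
#' @export
correctDynamic <- function(rawFrame, model, backgroundRegion = NULL,
                           marginCols = 20) {
  K <- length(model@eigenvalues)
  if (K == 0) return(list(frame = correctStatic(rawFrame, model),
                          weights = numeric(0)))
  nr <- nrow(rawFrame); nc <- ncol(rawFrame)
  if (is.null(backgroundRegion)) {
    m <- min(marginCols, floor(nc / 4))
    backgroundRegion <- matrix(FALSE, nr, nc)
    backgroundRegion[, c(seq_len(m), nc + 1 - seq_len(m))] <- TRUE
  }
  if (!any(backgroundRegion)) stop("background region is empty")
  flatNet <- model@flatMean - model@darkMean
  resid <- (rawFrame - model@darkMean - flatNet)[backgroundRegion]
  A <- matrix(model@eigenflats, nr * nc, K)[as.vector(backgroundRegion), ,
                                            drop = FALSE]
  w <- tryCatch(qr.solve(A, resid),
                error = function(e) NULL)
  if (is.null(w) || any(!is.finite(w))) {
    warning("singular background normal equations; using static correction")
    return(list(frame = correctStatic(rawFrame, model),
                weights = rep(NA_real_, K)))
  }
  eff <- flatNet + matrix(matrix(model@eigenflats, nr * nc, K) %*% w, nr, nc)
  floorv <- 1e-6 * median(eff)
  eff[eff < floorv] <- floorv
  list(frame = (rawFrame - model@darkMean) / eff, weights = as.numeric(w))
}

#' Correct a whole projection stack
#'
#' Applies static or dynamic flat-field correction to every projection of a
#' \linkS4class{ProjectionSet}, fitting the flat basis from the set's own
#' calibration frames.
#'
#' @param ps a \linkS4class{ProjectionSet}.
#' @param method "dynamic" or "static".
#' @param K eigen-flats for the dynamic method.
#' @param backgroundRegion,marginCols see \code{\link{correctDynamic}}.
#' @return array (n_proj x rows x cols) of transmission frames.
#' @export
correctProjections <- function(ps, method = c("dynamic", "static"), K = 5,
                               backgroundRegion = NULL, marginCols = 20) {
  method <- match.arg(method)
  darkMean <- apply(ps@darks, c(2, 3), mean)
  model <- fitFlatBasis(ps@flats, darkMean,
                        K = if (method == "static") 1 else K)
  n <- dim(ps@data)[1]
  out <- array(0, dim(ps@data))
  for (i in seq_len(n)) {
    fr <- matrix(ps@data[i, , ], dim(ps@data)[2], dim(ps@data)[3])
    out[i, , ] <- if (method == "static") correctStatic(fr, model) else
      correctDynamic(fr, model, backgroundRegion, marginCols)$frame
  }
  out
}

#' Ring-artifact score of a reconstructed slice
#'
#' The slice is resampled to polar coordinates about the given centre; rings
#' show up as narrow deviations of the angular-mean radial profile from its
#' moving-average baseline.  The score is the mean absolute deviation between
#' the two, so a constant (or smooth rotationally symmetric) slice scores
#' near 0 and planted concentric rings increase the score monotonically with
#' their amplitude.
#'
#' @param slice square matrix.
#' @param center (x, y) centre, 1-based; default the slice centre.
#' @param nAngles angular samples per radius.
#' @return nonnegative scalar.
#' @export
ringMetric <- function(slice, center = NULL, nAngles = 360) {
  n <- nrow(slice)
  if (is.null(center)) center <- c((n + 1) / 2, (ncol(slice) + 1) / 2)
  rmax <- floor(min(center[1], center[2], n - center[1],
                    ncol(slice) - center[2]) - 1)
  if (rmax < 5) stop("center too close to the slice edge")
  ang <- seq(0, 2 * pi, length.out = nAngles + 1)[seq_len(nAngles)]
  arr <- array(slice, c(dim(slice), 1))
  prof <- vapply(seq_len(rmax), function(r) {
    xs <- center[1] + r * cos(ang)
    ys <- center[2] + r * sin(ang)
    mean(sampleVolume(arr, xs, ys, rep(1, nAngles)))
  }, numeric(1))
  # moving-average baseline (reflected ends); rings are narrow in radius
  w <- 9
  ext <- c(rev(prof[seq_len(w)]), prof, rev(prof)[seq_len(w)])
  base <- stats::filter(ext, rep(1 / w, w), sides = 2)[w + seq_along(prof)]
  mean(abs(prof - base))
}

#' Stripe score of a sinogram
#'
#' Standard deviation of the detrended column means of the log-sinogram:
#' fixed-pattern (per-column) normalization errors appear as vertical
#' stripes, i.e. column-to-column jitter of the mean optical depth.
#'
#' @param sino matrix (angles x detector columns) of transmission values.
#' @return nonnegative scalar.
#' @export
stripeMetric <- function(sino) {
  cm <- colMeans(-log(pmax(sino, 1e-9)))
  sd(cm - stats::runmed(cm, 9))
}

setMethod("show", "FlatFieldModel", function(object) {
  cat(sprintf("FlatFieldModel: %d x %d px, K = %d eigen-flats\n",
              nrow(object@flatMean), ncol(object@flatMean),
              length(object@eigenvalues)))
  if (length(object@eigenvalues))
    cat("  eigenvalues:", sprintf("%.3g", object@eigenvalues), "\n")
})
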