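#' Single-material propagation transfer filter
#'
#' Fourier-domain factor \eqn{1 + (z\delta/\mu)|k|^2} of the transport-of-
#' intensity single-material model, with \eqn{|k|} in angular frequency
#' (rad/m).  The acquisition simulator multiplies contact-intensity spectra
#' by this factor (edge enhancement); \code{\link{paganinRetrieve}} divides
#' by it.  Both go through this one helper, so the two directions share the
#' frequency convention exactly.
#'
#' @param dims (rows, cols) of the frame.
#' @param optics an \linkS4class{OpticsConfig}.
#' @return matrix of filter values (>= 1, equal to 1 at DC).
#' @export
phaseTransferFilter <- function(dims, optics) {
  px <- optics@pixelSizeUm * 1e-6
  kr <- 2 * pi * fftfreq(dims[1], d = px)
  kc <- 2 * pi * fftfreq(dims[2], d = px)
  k2 <- outer(kr^2, kc^2, "+")
  1 + (optics@propagationDistanceM * optics@delta / optics@muInvM) * k2
}

# default reflective padding width: the transfer's characteristic length
defaultPhasePad <- function(optics) {
  px <- optics@pixelSizeUm * 1e-6
  sig <- optics@propagationDistanceM * optics@delta / optics@muInvM
  max(64, ceiling(2 * sqrt(sig) / px))
}

# apply the transfer (or its inverse) to a frame, optionally with reflective
# padding to mitigate wrap-around on truncated real data
phaseTransferApply <- function(frame, optics, inverse = FALSE, padPx = 0) {
  nr <- nrow(frame); nc <- ncol(frame)
  if (padPx > 0) frame <- padReflect(frame, padPx, padPx)
  fac <- phaseTransferFilter(dim(frame), optics)
  out <- ifft2(fft2(frame) * if (inverse) 1 / fac else fac)
  if (padPx > 0) out <- cropPad(out, padPx, padPx, nr, nc)
  out
}

#' Paganin single-distance phase retrieval
#'
#' Converts a flat-corrected (transmission) projection of a single-material
#' object into a thickness map:
#' \deqn{T = -\frac{1}{\mu}\,\ln\,\mathcal{F}^{-1}\!\left[
#'   \frac{\mathcal{F}[I]}{1 + (z\delta/\mu)|k|^2}\right]}
#' with \eqn{\mu = 4\pi\beta/\lambda}.  The filter has unit DC gain, so a
#' constant frame c retrieves \eqn{T = -\ln(c)/\mu} exactly.  Frames are
#' reflectively padded before filtering (default width
#' \code{max(64, 2 sqrt(z delta/mu) / pixel)} pixels, the filter's
#' characteristic length); pass \code{padPx = 0} for strictly periodic
#' frames, where the retrieval is the exact inverse of the simulator's edge
#' enhancement.
#'
#' @param frame normalized transmission frame (> 0; non-positive values are
#'   floored with a warning).
#' @param optics an \linkS4class{OpticsConfig}.
#' @param padPx reflective padding width in pixels, or NULL for the default.
#' @return list with \code{thicknessM} (metres) and \code{muT}
#'   (dimensionless retrieved optical depth).
#' @examples
#' opt <- OpticsConfig()
#' paganinRetrieve(matrix(0.8, 16, 16), opt)$muT[1, 1]  # -log(0.8)
#' @export
paganinRetrieve <- function(frame, optics, padPx = NULL) {
  mu <- optics@muInvM
  sig <- optics@propagationDistanceM * optics@delta / mu
  if (sig <= 0) stop("z * delta / mu must be positive")
  if (is.null(padPx)) padPx <- defaultPhasePad(optics)
  if (any(frame <= 0)) {
    warning(sprintf("floored %d non-positive transmission pixels",
                    sum(frame <= 0)))
    frame[frame <= 0] <- 1e-9
  }
  filt <- phaseTransferApply(frame, optics, inverse = TRUE, padPx = padPx)
  filt[filt <= 0] <- 1e-9
  muT <- -log(filt)
  list(thicknessM = muT / mu, muT = muT)
}
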