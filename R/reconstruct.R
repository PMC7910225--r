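# Filtered back-projection for parallel-beam data with arbitrary angles and
# offset rotation centers, plus the extended-FOV (360-degree) assembly.

# Ramp-filter sinogram rows (detector along columns). dt is the detector
# sample spacing in the length unit of choice; output units are 1/length.
rampFilterRows <- function(sino, dt, apodization = c("ramlak", "shepp")) {
  apodization <- match.arg(apodization)
  nt <- ncol(sino)
  n2 <- 2^ceiling(log2(max(2 * nt, 8)))
  # discrete Ram-Lak kernel (exact DC behaviour, unlike sampling |nu|)
  h <- numeric(n2)
  h[1] <- 1 / (4 * dt^2)
  nodd <- seq(1, n2 / 2, by = 2)
  h[nodd + 1] <- -1 / (pi * nodd * dt)^2
  h[n2 - nodd + 1] <- -1 / (pi * nodd * dt)^2
  resp <- Re(stats::fft(h)) * dt
  if (apodization == "shepp") {
    nu <- fftfreq(n2, d = dt)
    x <- nu * dt                       # nu / (2 * nyquist)
    w <- ifelse(x == 0, 1, sin(pi * x) / (pi * x))
    resp <- resp * w
  }
  # taper the pad region from the edge values to zero (instead of a hard
  # zero pad): laterally truncated projections (interior tomography)
  # otherwise acquire strong low-frequency bias from the filter
  P <- n2 - nt
  Pr <- floor(P / 2); Pl <- P - Pr
  padR <- if (Pr > 0)
    outer(sino[, nt], 0.5 * (1 + cos(pi * seq_len(Pr) / (Pr + 1)))) else NULL
  padL <- if (Pl > 0)
    outer(sino[, 1], 0.5 * (1 - cos(pi * seq_len(Pl) / (Pl + 1)))) else NULL
  ext <- cbind(sino, padR, padL)
  Q <- mvfft(t(ext))
  q <- Re(mvfft(Q * resp, inverse = TRUE)) / n2
  t(q)[, seq_len(nt), drop = FALSE]
}

# trapezoidal angular quadrature weights (radians) for sorted-or-not angles
angularWeights <- function(anglesDeg, fullTurnHalve = TRUE) {
  n <- length(anglesDeg)
  if (n == 1) return(pi)
  o <- order(anglesDeg)
  d <- diff(anglesDeg[o]) * pi / 180
  w <- (c(d[1], d) + c(d, d[length(d)])) / 2
  out <- numeric(n)
  out[o] <- w
  span <- diff(range(anglesDeg)) + mean(d) * 180 / pi
  # full-detector full-turn scans measure every ray twice; halve the weights
  # (the extended-FOV path keeps its half-detector rays at full weight)
  if (fullTurnHalve && span > 300) out <- out / 2
  out
}

#' Filtered back-projection of one sinogram
#'
#' Ramp-filtered back-projection with linear detector interpolation about the
#' rotation centre.  Angles need not be uniform; each projection is weighted
#' by its trapezoidal angular spacing (halved when the angles span a full
#' turn, since every ray is then measured twice).  The output slice is square
#' with side equal to the detector width, sampled on the detector grid so
#' that pixel j (0-based) lies at lateral offset \code{j - centerPx} pixels
#' from the axis.
#'
#' @param sino matrix (n_angles x cols) of retrieved optical depth
#'   (\eqn{\mu T}, dimensionless).
#' @param anglesDeg projection angles, degrees.
#' @param centerPx 0-based sub-pixel detector column of the rotation axis.
#' @param pixelSizeUm detector pixel size; output is in 1/m.
#' @param apodization "ramlak" or "shepp".
#' @return square matrix (cols x cols) of attenuation values, 1/m.
#' @export
fbpSlice <- function(sino, anglesDeg, centerPx = (ncol(sino) - 1) / 2,
                     pixelSizeUm = 1, apodization = c("ramlak", "shepp")) {
  stopifnot(nrow(sino) >= 2, all(is.finite(anglesDeg)))
  span <- diff(range(anglesDeg))
  if (span < 170)
    warning("angular coverage below ~170 degrees; limited-angle artifacts expected")
  px <- pixelSizeUm * 1e-6
  q <- rampFilterRows(sino, dt = px, apodization = apodization)
  q <- q * angularWeights(anglesDeg)
  nt <- ncol(sino)
  tv <- (seq_len(nt) - 1 - centerPx) * px
  backproject_cpp(t(q), tv, anglesDeg * pi / 180, tv, tv)
}

#' Extended field-of-view (360-degree) reconstruction
#'
#' Reconstructs a full-diameter slice stack from a 360-degree scan whose
#' rotation axis projects near one detector edge.  Every half-projection is
#' treated as an independent view at its true angle: stored angles plus
#' \code{epsDeg} added to the views beyond 180 degrees (the complementary-
#' pair offset).  For ramp filtering, each view's truncated row is completed
#' across the axis with its complementary view's data; for back-projection
#' the detector samples beyond the rotation centre are discarded (hard cut at
#' the centre, the default) or the doubly-measured band within
#' \code{centerPx} pixels of the axis is blended with linear angular-position
#' weights (\code{overlapMode = "weight"}).
#'
#' @param projections array (n_angles x rows x cols) of retrieved optical
#'   depth, or a matrix (n_angles x cols) for a single slice.
#' @param anglesDeg per-projection angles covering ~360 degrees.
#' @param centerPx 0-based rotation-axis column, near one detector side.
#' @param epsDeg extra angular offset of the complementary half; 0 when the
#'   supplied angles are already the true ones.
#' @param pixelSizeUm detector pixel size.
#' @param overlapMode "cut" or "weight".
#' @param apodization ramp filter window.
#' @return array (D x D x rows) with D = round(2 * (cols - centerPx)) when
#'   the axis is left of centre (mirrored otherwise); a matrix for
#'   single-slice input.  The axis maps to the slice centre.
#' @export
reconstructExtendedFov <- function(projections, anglesDeg, centerPx,
                                   epsDeg = 0, pixelSizeUm = 1,
                                   overlapMode = c("cut", "weight"),
                                   apodization = c("ramlak", "shepp")) {
  overlapMode <- match.arg(overlapMode)
  apodization <- match.arg(apodization)
  single <- length(dim(projections)) == 2
  if (single)
    projections <- array(projections, c(nrow(projections), 1,
                                        ncol(projections)))
  na <- dim(projections)[1]; nz <- dim(projections)[2]
  m <- dim(projections)[3]
  span <- diff(range(anglesDeg))
  if (span < 300)
    warning("extended-FOV assembly expects ~360-degree coverage")
  if (centerPx < 0 || centerPx > m - 1) stop("center outside the detector")
  flip <- centerPx > (m - 1) / 2
  if (flip) {
    projections <- projections[, , m:1, drop = FALSE]
    centerPx <- m - 1 - centerPx
  }
  theta <- anglesDeg + ifelse(anglesDeg >= 180, epsDeg, 0)
  px <- pixelSizeUm * 1e-6

  # complementary view of each view: nearest angle to theta + 180 (mod 360)
  comp <- vapply(seq_len(na), function(i) {
    d <- abs(((theta - (theta[i] + 180)) %% 360 + 540) %% 360 - 180)
    which.min(d)
  }, integer(1))

  # uniform extended detector grid (voxel units relative to the axis)
  tOwn <- seq_len(m) - 1 - centerPx          # own-sample offsets, px
  tmax <- m - 1 - centerPx
  tg <- seq(-ceiling(tmax), ceiling(tmax))   # integer grid, px
  ng <- length(tg)
  D <- round(2 * (m - centerPx))
  xs <- (seq_len(D) - (D + 1) / 2) * px

  cov <- max(centerPx, 0)                    # half-width of the doubled band
  wOut <- if (overlapMode == "cut") pmin(1, pmax(0, tg + 0.5)) else {
    if (cov < 1) pmin(1, pmax(0, tg + 0.5)) else
      pmin(1, pmax(0, (tg + cov) / (2 * cov)))
  }
  wts <- angularWeights(theta, fullTurnHalve = FALSE)

  out <- array(0, c(D, D, nz))
  for (z in seq_len(nz)) {
    sino <- matrix(projections[, z, ], na, m)
    # fill each view across the axis using its complementary view
    filled <- matrix(0, na, ng)
    for (i in seq_len(na)) {
      own <- interp1(sino[i, ], tg + 1 + centerPx, fill = NA)
      oth <- interp1(sino[comp[i], ], -tg + 1 + centerPx, fill = NA)
      v <- ifelse(is.na(own), oth, ifelse(is.na(oth), own,
                                          0.5 * (own + oth)))
      v[is.na(v)] <- 0
      filled[i, ] <- v
    }
    q <- rampFilterRows(filled, dt = px, apodization = apodization)
    q <- (q * wts) * rep(wOut, each = na)
    sl <- backproject_cpp(t(q), tg * px, theta * pi / 180, xs, xs)
    out[, , z] <- sl
  }
  if (flip) out <- out[D:1, , , drop = FALSE]
  if (single) out[, , 1] else out
}

#' Rotation-centre search by reconstruction sharpness
#'
#' Reconstructs one slice per candidate centre and scores each by image
#' sharpness (negative Shannon entropy of the normalized grey-level
#' histogram); the best-scoring candidate is refined to sub-step precision by
#' a parabolic fit through its neighbours.  A candidate range that excludes
#' the true centre yields a maximum on the range boundary, which is flagged.
#'
#' @param sino matrix (n_angles x cols), one slice's sinogram (\eqn{\mu T}).
#' @param anglesDeg projection angles, degrees.
#' @param candidateRangePx numeric (lo, hi) centre candidates, 0-based px.
#' @param stepPx candidate spacing, px.
#' @param pixelSizeUm detector pixel size.
#' @param nBins histogram bins for the entropy score.
#' @return list: \code{center_px}, \code{candidates}, \code{scores},
#'   \code{at_edge}.
#' @export
findCenter <- function(sino, anglesDeg, candidateRangePx, stepPx = 0.5,
                       pixelSizeUm = 1, nBins = 128) {
  m <- ncol(sino)
  if (candidateRangePx[1] < 0 || candidateRangePx[2] > m - 1)
    stop("candidate range outside the detector")
  cand <- seq(candidateRangePx[1], candidateRangePx[2], by = stepPx)
  scores <- vapply(cand, function(cc) {
    sl <- fbpSlice(sino, anglesDeg, centerPx = cc, pixelSizeUm = pixelSizeUm)
    sliceSharpness(sl, nBins)
  }, numeric(1))
  if (diff(range(scores)) < 1e-12 * max(abs(scores), 1)) {
    warning("flat center score curve; returning range midpoint")
    return(list(center_px = mean(candidateRangePx), candidates = cand,
                scores = scores, at_edge = FALSE))
  }
  b <- which.max(scores)
  atEdge <- b == 1L || b == length(cand)
  centre <- cand[b]
  if (!atEdge) {
    sm <- scores[b - 1]; sp <- scores[b + 1]
    den <- sm - 2 * scores[b] + sp
    if (den < 0) centre <- centre + 0.5 * (sm - sp) / den * stepPx
  }
  list(center_px = centre, candidates = cand, scores = scores,
       at_edge = atEdge)
}

# negative Shannon entropy of the normalized grey-level histogram
sliceSharpness <- function(slice, nBins = 128) {
  v <- as.vector(slice)
  r <- range(v)
  if (diff(r) == 0) return(0)
  h <- tabulate(pmin(nBins, 1L + floor((v - r[1]) / diff(r) * nBins)), nBins)
  p <- h / sum(h)
  p <- p[p > 0]
  sum(p * log(p))
}

#' Per-layer rotation centres by linear interpolation
#'
#' @param centerTopPx,centerBottomPx centres found for the top and bottom
#'   mosaic layers.
#' @param nLayers number of layers.
#' @return numeric vector: arithmetic progression from top to bottom
#'   inclusive.
#' @examples
#' interpolateCenters(100, 106, 7)
#' @export
interpolateCenters <- function(centerTopPx, centerBottomPx, nLayers) {
  stopifnot(nLayers >= 1)
  if (nLayers == 1) return((centerTopPx + centerBottomPx) / 2)
  seq(centerTopPx, centerBottomPx, length.out = nLayers)
}

#' Reconstruct one tile of a mosaic
#'
#' Chains flat-field correction (static or dynamic), Paganin phase retrieval
#' and extended-FOV filtered back-projection for one \linkS4class{ProjectionSet},
#' and positions the resulting volume in mosaic space.
#'
#' @param ps a \linkS4class{ProjectionSet} (stored angles are the true ones).
#' @param plan the \linkS4class{MosaicPlan} the tile belongs to.
#' @param optics an \linkS4class{OpticsConfig}.
#' @param correction "dynamic" or "static".
#' @param K eigen-flats for dynamic correction.
#' @param centerPx rotation-axis column; defaults to the set's recorded axis.
#' @param overlapMode,apodization see \code{\link{reconstructExtendedFov}}.
#' @param padPx phase-retrieval padding (NULL for the default).
#' @return A \linkS4class{TileVolume}.
#' @export
reconstructTile <- function(ps, plan, optics,
                            correction = c("dynamic", "static"), K = 5,
                            centerPx = NULL, overlapMode = "cut",
                            apodization = "ramlak", padPx = NULL) {
  correction <- match.arg(correction)
  if (is.null(centerPx)) centerPx <- ps@axisOffsetPx
  trans <- correctProjections(ps, method = correction, K = K)
  n <- dim(trans)[1]
  for (i in seq_len(n))
    trans[i, , ] <- paganinRetrieve(matrix(trans[i, , ], dim(trans)[2],
                                           dim(trans)[3]),
                                    optics, padPx = padPx)$muT
  vol <- reconstructExtendedFov(trans, ps@thetaDeg, centerPx, epsDeg = 0,
                                pixelSizeUm = ps@pixelSizeUm,
                                overlapMode = overlapMode,
                                apodization = apodization)
  D <- dim(vol)[1]
  vox_mm <- ps@pixelSizeUm * 1e-3
  g <- ps@gridIndex
  centreMm <- c(g[1] * plan@stepMm[1], g[2] * plan@stepMm[1],
                g[3] * plan@stepMm[2])
  origin <- centreMm - c(D / 2, D / 2, dim(vol)[3] / 2) * vox_mm
  new("TileVolume", vol = vol, voxelSizeUm = ps@pixelSizeUm,
      originMm = origin, gridIndex = g, timestampS = ps@timestampS)
}

setMethod("show", "TileVolume", function(object) {
  d <- dim(object@vol)
  cat(sprintf("TileVolume: %d x %d x %d voxels at %.3g um, tile (%s)\n",
              d[1], d[2], d[3], object@voxelSizeUm,
              paste(object@gridIndex, collapse = ",")))
  cat(sprintf("  origin %s mm, t = %.1f s\n",
              paste(sprintf("%.3f", object@originMm), collapse = ", "),
              object@timestampS))
})
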