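#' Construct a drifting illumination model
#'
#' The mean flat field is a smooth intensity profile at \code{level} expected
#' counts per pixel; drift components are smooth random zero-mean patterns,
#' orthonormalised over pixels, whose coefficients follow a stationary AR(1)
#' process.  This emulates the slow illumination variability (monochromator
#' vibrations) that static flat-fielding cannot catch.
#'
#' @param dims integer (rows, cols) of the detector.
#' @param K number of drift components.
#' @param relAmplitude RMS drift per pixel relative to the mean level.
#' @param componentSigma spatial correlation length (pixels) of the drift
#'   patterns; a few pixels, as for monochromator-vibration ripples.
#' @param ar1 lag-one autocorrelation of the coefficient process.
#' @param level mean photon counts per pixel at unit transmission.
#' @param darkLevel,darkSd mean and noise sd of the dark signal, counts.
#' @param seed integer seed.
#' @return An \linkS4class{IlluminationModel}.
#' @export
makeIlluminationModel <- function(dims, K = 3, relAmplitude = 0.02,
                                  componentSigma = 2, ar1 = 0.95,
                                  level = 5000, darkLevel = 100,
                                  darkSd = 2, seed = 1) {
  set.seed(as.integer(childSeed(seed, 2)) %% .Machine$integer.max)
  nr <- dims[1]; nc <- dims[2]
  prof <- outer(seq(-1, 1, length.out = nr)^2, seq(-1, 1, length.out = nc)^2,
                function(a, b) 1 - 0.08 * (a + b))
  meanFlat <- level * prof
  comps <- array(0, c(nr, nc, max(K, 0)))
  if (K > 0) {
    raw <- sapply(seq_len(K), function(k) {
      m <- gaussSmooth2d(matrix(rnorm(nr * nc), nr, nc),
                         sigma = componentSigma)
      as.vector(m - mean(m))
    })
    q <- qr.Q(qr(raw))
    # re-centre (QR can reintroduce a tiny mean) and re-orthonormalise
    q <- sweep(q, 2, colMeans(q))
    q <- qr.Q(qr(q))
    comps <- array(q, c(nr, nc, K))
  }
  new("IlluminationModel", meanFlat = meanFlat, components = comps,
      coefAmplitude = relAmplitude * level * sqrt(nr * nc), coefAr1 = ar1,
      darkMean = matrix(darkLevel, nr, nc), darkSd = darkSd,
      countsPerPixel = level)
}

#' Number of drift components of an illumination model
#' @param illum an \linkS4class{IlluminationModel}.
#' @export
nComponents <- function(illum) {
  d <- dim(illum@components)
  if (length(d) < 3) 0L else d[3]
}

#' AR(1) drift coefficient series
#'
#' Stationary AR(1) draws for each drift component over \code{n} frames.
#' @param illum an \linkS4class{IlluminationModel}.
#' @param n number of frames.
#' @param seed integer seed.
#' @return n x K matrix of coefficients (counts scale).
#' @export
illumCoefficients <- function(illum, n, seed = 1) {
  K <- nComponents(illum)
  if (K == 0) return(matrix(0, n, 0))
  set.seed(as.integer(childSeed(seed, 3)) %% .Machine$integer.max)
  rho <- illum@coefAr1
  amp <- illum@coefAmplitude
  co <- matrix(0, n, K)
  co[1, ] <- rnorm(K, sd = amp)
  if (n > 1) {
    innov <- amp * sqrt(1 - rho^2)
    for (t in 2:n) co[t, ] <- rho * co[t - 1, ] + rnorm(K, sd = innov)
  }
  co
}

# incident flat field at given drift coefficients
flatAt <- function(illum, coefs) {
  f <- illum@meanFlat
  K <- nComponents(illum)
  if (K > 0 && length(coefs))
    for (k in seq_len(K)) f <- f + coefs[k] * illum@components[, , k]
  f
}

#' Construct a smooth time-dependent deformation model
#'
#' @param volDims integer (nx, ny, nz) voxel grid the field applies to.
#' @param controlPoints control points per axis.
#' @param ratePerS displacement amplitude growth rate, voxels per second.
#' @param seed integer seed.
#' @return A \linkS4class{DeformationModel}.
#' @export
makeDeformationModel <- function(volDims, controlPoints = 5, ratePerS = 0.02,
                                 seed = 1) {
  set.seed(as.integer(childSeed(seed, 4)) %% .Machine$integer.max)
  ncp <- rep(controlPoints, 3)
  ctrl <- array(rnorm(prod(ncp) * 3), c(ncp, 3))
  for (c3 in 1:3) ctrl[, , , c3] <- gaussSmooth3d(ctrl[, , , c3], sigma = 1)
  m <- max(sqrt(apply(ctrl^2, 1:3, sum)))
  ctrl <- ctrl / m # unit peak magnitude
  new("DeformationModel", controlDisp = ctrl, volDims = as.integer(volDims),
      ratePerS = ratePerS)
}

#' Evaluate a deformation field
#'
#' Displacement (voxels) at the given voxel coordinates and time; zero at
#' t = 0 and growing linearly with the model's rate.
#'
#' @param model a \linkS4class{DeformationModel}.
#' @param timeS time in seconds.
#' @param xs,ys,zs 1-based voxel coordinates (equal length).
#' @return length(xs) x 3 matrix of displacements.
#' @export
deformationAt <- function(model, timeS, xs, ys, zs) {
  amp <- model@ratePerS * timeS
  n <- length(xs)
  if (amp == 0) return(matrix(0, n, 3))
  d <- model@volDims
  ncp <- dim(model@controlDisp)[1:3]
  tx <- (xs - 1) / max(d[1] - 1, 1) * (ncp[1] - 1) + 1
  ty <- (ys - 1) / max(d[2] - 1, 1) * (ncp[2] - 1) + 1
  tz <- (zs - 1) / max(d[3] - 1, 1) * (ncp[3] - 1) + 1
  out <- matrix(0, n, 3)
  for (c3 in 1:3) {
    comp <- array(model@controlDisp[, , , c3], ncp)
    out[, c3] <- amp * sampleVolume(comp, tx, ty, tz, fill = 0)
  }
  out
}

#' Warp a volume by a deformation model at a given time
#'
#' The warped volume samples the original at \code{p + u(p, t)} (pull-back
#' convention).
#' @param vol 3-D array.
#' @param model a \linkS4class{DeformationModel} (defined on \code{dim(vol)}).
#' @param timeS time, seconds.
#' @export
warpVolume <- function(vol, model, timeS) {
  if (model@ratePerS * timeS == 0) return(vol)
  d <- dim(vol)
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  u <- deformationAt(model, timeS, g$x, g$y, g$z)
  v <- sample_trilinear_cpp(vol, g$x - 1 + u[, 1], g$y - 1 + u[, 2],
                            g$z - 1 + u[, 3], 0)
  array(v, d)
}

#' Parallel-beam line-integral projection
#'
#' Discrete line integrals of the attenuation volume along rays perpendicular
#' to the detector at each angle, about a vertical rotation axis through the
#' volume centre.  Detector column j (0-based) sits at lateral offset
#' \code{j - axisOffsetPx} pixels from the axis.  Rotation is mathematically
#' positive viewed from +z.  Output values are dimensionless optical depths
#' (\eqn{\mu} times length).
#'
#' @param x a \linkS4class{Phantom} or a 3-D attenuation array (1/m).
#' @param anglesDeg projection angles, degrees.
#' @param axisOffsetPx 0-based detector column of the rotation axis; default
#'   detector centre.
#' @param detectorWidthPx detector columns; default \code{dim(x)[1]}.
#' @param voxelSizeUm voxel size (required when \code{x} is a bare array).
#' @return array (n_angles, n_rows = nz, detectorWidthPx).
#' @export
projectParallel <- function(x, anglesDeg, axisOffsetPx = NULL,
                            detectorWidthPx = NULL, voxelSizeUm = NULL) {
  if (is(x, "Phantom")) {
    vol <- x@vol
    voxelSizeUm <- x@voxelSizeUm
  } else {
    vol <- x
    if (is.null(voxelSizeUm)) stop("voxelSizeUm required for bare arrays")
  }
  stopifnot(all(is.finite(anglesDeg)))
  d <- dim(vol)
  if (is.null(detectorWidthPx)) detectorWidthPx <- d[1]
  if (is.null(axisOffsetPx)) axisOffsetPx <- (detectorWidthPx - 1) / 2
  if (axisOffsetPx < 0 || axisOffsetPx > detectorWidthPx - 1)
    stop("axis offset outside the detector")
  sino <- forward_project_cpp(vol, anglesDeg * pi / 180,
                              (d[1] - 1) / 2, (d[2] - 1) / 2,
                              axisOffsetPx, as.integer(detectorWidthPx))
  sino * voxelSizeUm * 1e-6
}

#' Apply edge enhancement, illumination and noise to an optical-depth frame
#'
#' Converts one projection's optical depth to a raw detector frame: the
#' contact intensity \code{exp(-depth)} gets the single-material propagation
#' transfer (multiplication of its Fourier spectrum by
#' \eqn{1 + (z\delta/\mu)|k|^2}, the inverse of the phase-retrieval filter,
#' applied through the shared helper so both directions use one frequency
#' convention), is multiplied by the drifting incident flat field, and the
#' dark offset plus Poisson photon and Gaussian read noise are added.  The
#' transfer uses the same reflective padding as the retrieval (\code{padPx});
#' with \code{padPx = 0} (periodic frames) retrieval is its exact inverse.
#'
#' @param opticalDepth 2-D matrix (rows x cols) of \eqn{\mu T}.
#' @param optics an \linkS4class{OpticsConfig}.
#' @param illum an \linkS4class{IlluminationModel}.
#' @param coefs drift coefficients for this frame (length K; default 0).
#' @param noise logical; add Poisson/Gaussian noise?
#' @param noiseSeed integer seed used when \code{noise} is TRUE.
#' @param padPx reflective padding width for the transfer; NULL for the
#'   shared default.
#' @return raw detector frame (counts).
#' @export
applyContrastAndIllumination <- function(opticalDepth, optics, illum,
                                         coefs = NULL, noise = TRUE,
                                         noiseSeed = 1, padPx = NULL) {
  stopifnot(optics@delta > 0, optics@beta > 0)
  if (is.null(padPx)) padPx <- defaultPhasePad(optics)
  intensity <- exp(-opticalDepth)
  enh <- phaseTransferApply(intensity, optics, inverse = FALSE, padPx = padPx)
  if (is.null(coefs)) coefs <- rep(0, nComponents(illum))
  lambda <- enh * flatAt(illum, coefs)
  lambda[lambda < 0] <- 0
  if (noise) {
    set.seed(as.integer(childSeed(noiseSeed, 5)) %% .Machine$integer.max)
    frame <- matrix(rpois(length(lambda), lambda), nrow(lambda)) +
      illum@darkMean + matrix(rnorm(length(lambda), sd = illum@darkSd),
                              nrow(lambda))
  } else {
    frame <- lambda + illum@darkMean
  }
  nbad <- sum(frame <= 0)
  if (nbad > 0) {
    message(sprintf("clipped %d non-positive pixels to epsilon", nbad))
    frame[frame <= 0] <- 1e-6 * max(frame)
  }
  frame
}

#' Simulate a full wide-field mosaic acquisition
#'
#' For each tile of the plan (in acquisition order) the phantom is warped by
#' the deformation model at the tile's predicted start time, cropped to the
#' tile's physical extent plus a margin, and projected over 360 degrees with
#' the rotation axis at \code{axisOffsetPx}.  Complementary projections
#' \eqn{\theta} and \eqn{180 + \theta} carry an extra angular offset
#' \code{epsDeg}; the stored angle arrays are the true angles (nominal plus
#' offset).  Each tile is packaged with one shared set of calibration frames
#' (recorded once at plan start) and its timestamp.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param plan a \linkS4class{MosaicPlan} whose tiles lie inside the phantom.
#' @param optics an \linkS4class{OpticsConfig}.
#' @param illum an \linkS4class{IlluminationModel} sized (nz_crop rows are
#'   taken from its detector rows; dims must be (rows, detectorWidthPx)).
#' @param deform a \linkS4class{DeformationModel} (on the phantom grid), or
#'   NULL for a static sample.
#' @param nProj projections per tile over 360 degrees.
#' @param seed master seed; all randomness is derived from it.
#' @param detectorWidthPx detector columns.
#' @param axisOffsetPx 0-based rotation-axis column (near one edge for
#'   extended-FOV scans).
#' @param epsDeg complementary-pair angular offset, degrees.
#' @param nDark,nFlat calibration frame counts.
#' @param marginFrac crop margin around the tile, fraction of tile width;
#'   the default keeps the whole phantom in the beam (true local
#'   tomography), clamped to the phantom bounds.
#' @param phantomOriginMm mm position of phantom voxel (1,1,1) centre in
#'   mosaic space; default places the first tile's lower corner at the
#'   phantom's lower corner.
#' @param noise logical; add detector noise?
#' @param dir if non-NULL, each tile is also written there via
#'   \code{\link{writeProjectionSet}}.
#' @return list of \linkS4class{ProjectionSet}, in acquisition order.
#' @export
simulateMosaic <- function(phantom, plan, optics, illum, deform = NULL,
                           nProj = 400, seed = 1, detectorWidthPx,
                           axisOffsetPx, epsDeg = 0.04565, nDark = 50,
                           nFlat = 300, marginFrac = 100,
                           phantomOriginMm = NULL, noise = TRUE, dir = NULL) {
  stopifnot(nProj >= 2)
  vox_mm <- phantom@voxelSizeUm * 1e-3
  d <- dim(phantom@vol)
  if (is.null(phantomOriginMm))
    phantomOriginMm <- -plan@tileExtentMm / 2
  tiles <- planTiles(plan)

  # nominal angles over 360 degrees plus the complementary-pair offset
  nominal <- seq(0, 360, length.out = nProj + 1)[seq_len(nProj)]
  theta <- nominal + ifelse(nominal >= 180, epsDeg, 0)

  # one-off calibration frames
  set.seed(as.integer(childSeed(seed, 6)) %% .Machine$integer.max)
  nr <- nrow(illum@meanFlat); nc <- ncol(illum@meanFlat)
  if (nc != detectorWidthPx)
    stop("illumination model width must match detectorWidthPx")
  darks <- array(0, c(nDark, nr, nc))
  for (i in seq_len(nDark))
    darks[i, , ] <- illum@darkMean +
      matrix(rnorm(nr * nc, sd = illum@darkSd), nr)
  flatCoefs <- illumCoefficients(illum, nFlat, seed = childSeed(seed, 7))
  flats <- array(0, c(nFlat, nr, nc))
  for (i in seq_len(nFlat)) {
    lam <- flatAt(illum, flatCoefs[i, ])
    fr <- if (noise) matrix(rpois(nr * nc, pmax(lam, 0)), nr) else lam
    flats[i, , ] <- fr + illum@darkMean +
      if (noise) matrix(rnorm(nr * nc, sd = illum@darkSd), nr) else 0
  }

  sets <- vector("list", nrow(tiles))
  for (r in seq_len(nrow(tiles))) {
    tile <- tiles[r, ]
    t0 <- tile$predicted_start_s
    centreMm <- c(tile$x_mm, tile$y_mm, tile$z_mm)
    half <- plan@tileExtentMm / 2 * (1 + 2 * marginFrac * c(1, 1, 0))
    loMm <- centreMm - half; hiMm <- centreMm + half
    lo <- (loMm - phantomOriginMm) / vox_mm + 1
    hi <- (hiMm - phantomOriginMm) / vox_mm + 1
    loT <- (centreMm - plan@tileExtentMm / 2 - phantomOriginMm) / vox_mm + 1
    hiT <- (centreMm + plan@tileExtentMm / 2 - phantomOriginMm) / vox_mm + 1
    if (any(loT < 0.5) || any(hiT > d + 0.5))
      stop("tile outside phantom bounds")
    lo <- pmax(1L, floor(lo)); hi <- pmin(d, ceiling(hi))
    crop <- phantom@vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    if (!is.null(deform) && deform@ratePerS * t0 > 0) {
      dc <- dim(crop)
      g <- expand.grid(x = seq_len(dc[1]), y = seq_len(dc[2]),
                       z = seq_len(dc[3]))
      gx <- g$x + lo[1] - 1; gy <- g$y + lo[2] - 1; gz <- g$z + lo[3] - 1
      u <- deformationAt(deform, t0, gx, gy, gz)
      v <- sample_trilinear_cpp(phantom@vol, gx - 1 + u[, 1],
                                gy - 1 + u[, 2], gz - 1 + u[, 3], 0)
      crop <- array(v, dc)
    }
    # rotation axis: vertical line through the tile centre
    axisVoxX <- (centreMm[1] - phantomOriginMm[1]) / vox_mm + 1 - lo[1]
    axisVoxY <- (centreMm[2] - phantomOriginMm[2]) / vox_mm + 1 - lo[2]
    depth <- forward_project_cpp(crop, theta * pi / 180, axisVoxX, axisVoxY,
                                 axisOffsetPx, as.integer(detectorWidthPx)) *
      vox_mm * 1e-3
    nzc <- dim(crop)[3]
    if (nzc > nr) stop("illumination model has fewer rows than the tile")
    rowSel <- seq_len(nzc)
    projCoefs <- illumCoefficients(illum, nProj,
                                   seed = childSeed(seed, 100 + r))
    raw <- array(0, c(nProj, nzc, nc))
    for (i in seq_len(nProj)) {
      fr <- applyContrastAndIllumination(
        matrix(depth[i, , ], nzc, nc), optics,
        subsetIllum(illum, rowSel), coefs = projCoefs[i, ], noise = noise,
        noiseSeed = childSeed(seed, 1000 * r + i))
      raw[i, , ] <- fr
    }
    ps <- new("ProjectionSet", data = raw,
              darks = darks[, rowSel, , drop = FALSE],
              flats = flats[, rowSel, , drop = FALSE],
              thetaDeg = theta, pixelSizeUm = phantom@voxelSizeUm,
              timestampS = t0,
              gridIndex = as.integer(c(tile$i, tile$j, tile$k)),
              axisOffsetPx = axisOffsetPx, epsDeg = epsDeg)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      writeProjectionSet(ps, file.path(dir, sprintf("tile_%03d", r - 1)))
    }
    sets[[r]] <- ps
  }
  sets
}

# restrict an illumination model to a subset of detector rows
subsetIllum <- function(illum, rows) {
  K <- nComponents(illum)
  comps <- if (K > 0) illum@components[rows, , , drop = FALSE] else
    array(0, c(length(rows), ncol(illum@meanFlat), 0))
  # row subsetting breaks exact orthonormality/zero-mean; bypass validity
  obj <- illum
  obj@meanFlat <- illum@meanFlat[rows, , drop = FALSE]
  obj@components <- comps
  obj@darkMean <- illum@darkMean[rows, , drop = FALSE]
  obj
}

setMethod("show", "ProjectionSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("ProjectionSet: %d projections of %d x %d px\n", d[1], d[2],
              d[3]))
  cat(sprintf("  tile (%s), axis at %.2f px, t = %.1f s, %d darks, %d flats\n",
              paste(object@gridIndex, collapse = ","), object@axisOffsetPx,
              object@timestampS, dim(object@darks)[1], dim(object@flats)[1]))
})
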