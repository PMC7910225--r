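#' @useDynLib mosaicCT, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm rpois runif median mad sd fft mvfft approx coef lm setNames quantile
#' @importFrom utils head tail
NULL

## ---------------------------------------------------------------------------
## Timing of the mosaic acquisition
## ---------------------------------------------------------------------------

#' Per-step timing of a mosaic acquisition
#'
#' Wall-clock model of a wide-field mosaic scan: the (average) duration of one
#' tomographic scan including software/readout overheads, the constant motor
#' speeds of the vertical and horizontal translation stages, the per-motion
#' settle/acceleration overhead, and the one-off calibration (dark/flat) time
#' recorded before the mosaic starts.
#'
#' @slot scanTimeS per-tomogram wall time in seconds, including overheads.
#' @slot verticalSpeedUmS vertical stage speed, micrometres per second.
#' @slot horizontalSpeedUmS horizontal stage speed, micrometres per second.
#' @slot moveOverheadS settle/accelerate overhead added to every motion, s.
#' @slot calibrationTimeS one-off dark/flat recording time at plan start, s.
#' @export
setClass("TimingModel", representation(
  scanTimeS = "numeric",
  verticalSpeedUmS = "numeric",
  horizontalSpeedUmS = "numeric",
  moveOverheadS = "numeric",
  calibrationTimeS = "numeric"
), validity = function(object) {
  v <- c(object@scanTimeS, object@verticalSpeedUmS, object@horizontalSpeedUmS,
         object@moveOverheadS, object@calibrationTimeS)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all timing fields must be finite and > 0")
  TRUE
})

#' @describeIn TimingModel Constructor. Defaults are the per-step averages of
#'   a fast wide-field lung mosaic protocol: 9.0 s per 360-degree scan,
#'   550/220 um/s stage speeds, 3 s per-move overhead, and 5 s to record the
#'   one-off calibration frames (350 frames at 2.5 ms plus shutter/readout
#'   overhead).
#' @param scanTimeS,verticalSpeedUmS,horizontalSpeedUmS,moveOverheadS,calibrationTimeS
#'   see the slot documentation.
#' @export
TimingModel <- function(scanTimeS = 9.0, verticalSpeedUmS = 550,
                        horizontalSpeedUmS = 220, moveOverheadS = 3.0,
                        calibrationTimeS = 5.0) {
  new("TimingModel", scanTimeS = scanTimeS, verticalSpeedUmS = verticalSpeedUmS,
      horizontalSpeedUmS = horizontalSpeedUmS, moveOverheadS = moveOverheadS,
      calibrationTimeS = calibrationTimeS)
}

## ---------------------------------------------------------------------------
## Mosaic plan
## ---------------------------------------------------------------------------

#' Tiling plan of a 3-D mosaic of wide-field scans
#'
#' Ordered tile poses for a mosaic acquisition.  Tiles are laid out on a
#' regular lattice with horizontal step \code{stepMm[1]} (x and y) and
#' vertical step \code{stepMm[2]} (z), both smaller than the corresponding
#' tile extent so that neighbouring tiles overlap.  The acquisition order is
#' column-wise (vertical axis fastest) and zigzag along every axis, so each
#' motion moves to an adjacent unmeasured tile.
#'
#' @slot gridShape integer (nx, ny, nz) tile counts along width/length/height.
#' @slot tileExtentMm numeric (w, l, h) physical extent of one tile, mm.
#' @slot stepMm numeric (horizontal, vertical) lattice steps, mm.
#' @slot pixelSizeUm detector/voxel pixel size, micrometres.
#' @slot tiles data.frame with one row per tile: grid indices \code{i,j,k}
#'   (0-based), centre position \code{x_mm,y_mm,z_mm}, \code{order_index}
#'   (0-based acquisition rank) and \code{predicted_start_s}.
#' @export
setClass("MosaicPlan", representation(
  gridShape = "integer",
  tileExtentMm = "numeric",
  stepMm = "numeric",
  pixelSizeUm = "numeric",
  tiles = "data.frame"
), validity = function(object) {
  g <- object@gridShape
  if (length(g) != 3L || any(g < 1L)) return("gridShape must be 3 integers >= 1")
  if (nrow(object@tiles) != prod(g)) return("tile count must equal nx*ny*nz")
  st <- c(object@stepMm[1], object@stepMm[1], object@stepMm[2])
  if (any(st > object@tileExtentMm + 1e-12))
    return("step must not exceed tile extent (tiles must overlap or abut)")
  oi <- sort(object@tiles$order_index)
  if (!identical(as.integer(oi), seq_len(nrow(object@tiles)) - 1L))
    return("order_index must be unique and contiguous from 0")
  TRUE
})

## ---------------------------------------------------------------------------
## Optics
## ---------------------------------------------------------------------------

#' X-ray optics configuration for single-distance phase contrast
#'
#' Beam energy, sample-to-detector propagation distance, effective pixel size
#' and the single-material refractive index \eqn{n = 1 - \delta + i\beta}.
#' The wavelength \eqn{\lambda = hc/E} and the linear attenuation coefficient
#' \eqn{\mu = 4\pi\beta/\lambda} are derived at construction time.
#'
#' @slot energyKeV photon energy, keV.
#' @slot propagationDistanceM sample-to-detector distance, metres.
#' @slot pixelSizeUm effective detector pixel size, micrometres.
#' @slot delta refractive index decrement \eqn{\delta}.
#' @slot beta absorption index \eqn{\beta}.
#' @slot wavelengthM derived wavelength, metres.
#' @slot muInvM derived attenuation coefficient \eqn{4\pi\beta/\lambda}, 1/m.
#' @export
setClass("OpticsConfig", representation(
  energyKeV = "numeric",
  propagationDistanceM = "numeric",
  pixelSizeUm = "numeric",
  delta = "numeric",
  beta = "numeric",
  wavelengthM = "numeric",
  muInvM = "numeric"
), validity = function(object) {
  v <- c(object@energyKeV, object@propagationDistanceM, object@pixelSizeUm,
         object@delta, object@beta, object@wavelengthM, object@muInvM)
  if (any(!is.finite(v)) || any(v <= 0)) return("all optics fields must be > 0")
  lam <- .hc_eV_m / (object@energyKeV * 1e3)
  if (abs(lam - object@wavelengthM) / lam > 1e-6)
    return("wavelength inconsistent with energy")
  mu <- 4 * pi * object@beta / object@wavelengthM
  if (abs(mu - object@muInvM) / mu > 1e-6)
    return("mu inconsistent with beta and wavelength")
  TRUE
})

# hc in eV*m (CODATA)
.hc_eV_m <- 1.23984198e-6

#' @describeIn OpticsConfig Constructor.  Defaults are the empirical values of
#'   a 21 keV lung imaging protocol: 100 mm propagation distance, 2.75 um
#'   pixels, delta = 2.0e-7, beta = 2.8e-10.
#' @param energyKeV,propagationDistanceM,pixelSizeUm,delta,beta see slots.
#' @export
OpticsConfig <- function(energyKeV = 21, propagationDistanceM = 0.1,
                         pixelSizeUm = 2.75, delta = 2.0e-7, beta = 2.8e-10) {
  lam <- .hc_eV_m / (energyKeV * 1e3)
  new("OpticsConfig", energyKeV = energyKeV,
      propagationDistanceM = propagationDistanceM, pixelSizeUm = pixelSizeUm,
      delta = delta, beta = beta, wavelengthM = lam,
      muInvM = 4 * pi * beta / lam)
}

## ---------------------------------------------------------------------------
## Phantom and simulation models
## ---------------------------------------------------------------------------

#' Synthetic attenuation phantom with ground-truth air bookkeeping
#'
#' @slot vol 3-D numeric array of linear attenuation values, 1/m.
#' @slot voxelSizeUm isotropic voxel size, micrometres.
#' @slot airMask logical array marking air voxels (mu = 0 up to the
#'   partial-volume smoothing of the attenuation map at mask boundaries).
#' @slot lungMask logical array marking the foam (lung) carving region; the
#'   realized air fraction is counted over this region.
#' @slot airVolumeMm3 ground-truth air volume: mask count times voxel volume.
#' @slot muTissue,muBone attenuation of the tissue and bone compartments, 1/m.
#' @export
setClass("Phantom", representation(
  vol = "array",
  voxelSizeUm = "numeric",
  airMask = "array",
  lungMask = "array",
  airVolumeMm3 = "numeric",
  muTissue = "numeric",
  muBone = "numeric"
), validity = function(object) {
  if (!identical(dim(object@vol), dim(object@airMask)))
    return("airMask and vol dimensions differ")
  if (any(object@vol < 0)) return("attenuation must be >= 0")
  vox_mm3 <- (object@voxelSizeUm * 1e-3)^3
  if (abs(object@airVolumeMm3 - sum(object@airMask) * vox_mm3) >
      1e-6 * max(object@airVolumeMm3, vox_mm3))
    return("airVolumeMm3 must equal mask count times voxel volume")
  TRUE
})

#' Low-rank drifting illumination model
#'
#' The incident flat field at frame t is
#' \code{meanFlat + sum_k c_k(t) * components[,,k]} with the coefficients
#' c_k(t) following a stationary AR(1) process of standard deviation
#' \code{coefAmplitude} and lag-one correlation \code{coefAr1}.  Detector
#' frames add a dark offset, Poisson photon noise (at \code{countsPerPixel}
#' mean counts for unit transmission) and Gaussian read noise.
#'
#' @slot meanFlat mean flat field (2-D, arbitrary intensity units > 0).
#' @slot components 3-D array (rows x cols x K) of zero-mean drift patterns.
#' @slot coefAmplitude stationary standard deviation of the coefficients.
#' @slot coefAr1 lag-one autocorrelation of the coefficient process, [0,1).
#' @slot darkMean mean dark frame (2-D).
#' @slot darkSd dark/read noise standard deviation.
#' @slot countsPerPixel mean photon counts per pixel at unit transmission.
#' @export
setClass("IlluminationModel", representation(
  meanFlat = "matrix",
  components = "array",
  coefAmplitude = "numeric",
  coefAr1 = "numeric",
  darkMean = "matrix",
  darkSd = "numeric",
  countsPerPixel = "numeric"
), validity = function(object) {
  if (any(object@meanFlat <= 0)) return("mean flat must be > 0 everywhere")
  K <- nComponents(object)
  if (K > 0) {
    cm <- apply(object@components, 3, mean)
    if (any(abs(cm) > 1e-8 * max(abs(object@components))))
      return("drift components must have zero spatial mean")
  }
  TRUE
})

#' Smooth, slowly growing tissue deformation model
#'
#' A random smooth displacement field defined on a coarse control-point grid,
#' scaled linearly in time: the displacement at time t is
#' \code{ratePerS * t} voxels times a fixed unit-amplitude smooth pattern.
#' The field is zero at t = 0 and its magnitude is nondecreasing in time,
#' emulating slow post-mortem tissue relaxation between mosaic tiles.
#'
#' @slot controlDisp 4-D array (ncx x ncy x ncz x 3) of unit-scale control
#'   point displacements.
#' @slot volDims dimensions of the voxel grid the field applies to.
#' @slot ratePerS displacement amplitude growth, voxels per second.
#' @export
setClass("DeformationModel", representation(
  controlDisp = "array",
  volDims = "integer",
  ratePerS = "numeric"
), validity = function(object) {
  if (length(dim(object@controlDisp)) != 4L || dim(object@controlDisp)[4] != 3L)
    return("controlDisp must be (ncx, ncy, ncz, 3)")
  if (object@ratePerS < 0) return("ratePerS must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## Projection data and calibration
## ---------------------------------------------------------------------------

#' One tile's raw projections with calibration frames
#'
#' @slot data raw projections, array (n_proj x rows x cols).
#' @slot darks dark frames, array (n_dark x rows x cols).
#' @slot flats flat frames, array (n_flat x rows x cols).
#' @slot thetaDeg per-projection rotation angles, degrees (true angles,
#'   including any complementary-pair offset).
#' @slot pixelSizeUm detector pixel size, micrometres.
#' @slot timestampS acquisition start time within the mosaic, seconds.
#' @slot gridIndex integer (i, j, k) tile grid index.
#' @slot axisOffsetPx detector column (0-based, sub-pixel) of the rotation
#'   axis.
#' @slot epsDeg complementary-pair angular offset used when simulating, deg.
#' @export
setClass("ProjectionSet", representation(
  data = "array",
  darks = "array",
  flats = "array",
  thetaDeg = "numeric",
  pixelSizeUm = "numeric",
  timestampS = "numeric",
  gridIndex = "integer",
  axisOffsetPx = "numeric",
  epsDeg = "numeric"
), validity = function(object) {
  if (dim(object@data)[1] != length(object@thetaDeg))
    return("thetaDeg length must match number of projections")
  if (!all(is.finite(object@thetaDeg))) return("angles must be finite")
  TRUE
})

#' Principal-component flat-field model
#'
#' Mean dark and flat frames plus the leading eigenvectors ("eigen-flats") of
#' the pixel covariance of a dark-subtracted flat-field stack, used for
#' dynamic flat-field correction.
#'
#' @slot darkMean,flatMean mean calibration frames (2-D).
#' @slot eigenflats array (rows x cols x K), mutually orthonormal over pixels.
#' @slot eigenvalues nonincreasing covariance eigenvalues, length K.
#' @export
setClass("FlatFieldModel", representation(
  darkMean = "matrix",
  flatMean = "matrix",
  eigenflats = "array",
  eigenvalues = "numeric"
), validity = function(object) {
  K <- length(object@eigenvalues)
  if (K > 0) {
    if (dim(object@eigenflats)[3] != K)
      return("eigenflats third dimension must equal length(eigenvalues)")
    if (is.unsorted(rev(object@eigenvalues)))
      return("eigenvalues must be nonincreasing")
    U <- matrix(object@eigenflats, ncol = K)
    G <- crossprod(U)
    if (max(abs(G - diag(K))) > 1e-6)
      return("eigen-flats must be orthonormal over pixels")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Reconstructed volumes, stitching, segmentation
## ---------------------------------------------------------------------------

#' A reconstructed tile volume positioned in mosaic space
#'
#' @slot vol 3-D numeric voxel array (x, y, z).
#' @slot voxelSizeUm isotropic voxel size, micrometres.
#' @slot originMm mosaic-space position (mm) of the voxel (1,1,1) corner.
#' @slot gridIndex integer (i, j, k) tile grid index.
#' @slot timestampS acquisition time of the tile, seconds.
#' @export
setClass("TileVolume", representation(
  vol = "array",
  voxelSizeUm = "numeric",
  originMm = "numeric",
  gridIndex = "integer",
  timestampS = "numeric"
))

#' Local displacement field between a pair of tiles
#'
#' Control points are voxel coordinates in the reference (earlier) tile;
#' each shift maps a reference-tile location to the corresponding location in
#' the moving tile, in voxels, total (rigid part included).
#'
#' @slot points n x 3 matrix of control point coordinates (1-based voxels).
#' @slot shifts n x 3 matrix of displacement vectors, voxels.
#' @slot valid logical flags per control point.
#' @slot scores similarity (NCC) score per control point.
#' @slot spacingVox control grid spacing, voxels.
#' @export
setClass("DisplacementField", representation(
  points = "matrix",
  shifts = "matrix",
  valid = "logical",
  scores = "numeric",
  spacingVox = "numeric"
), validity = function(object) {
  n <- nrow(object@points)
  if (nrow(object@shifts) != n || length(object@valid) != n ||
      length(object@scores) != n)
    return("points, shifts, valid and scores must agree in length")
  TRUE
})

#' Fused mosaic volume with overlap statistics
#'
#' @slot fused fused voxel array.
#' @slot voxelSizeUm voxel size, micrometres.
#' @slot originMm mosaic-space position (mm) of the fused voxel (1,1,1).
#' @slot stdMap per-voxel standard deviation of overlapping contributing
#'   values (population convention); zero where fewer than two tiles
#'   contribute.
#' @slot provenance integer array: number of tiles contributing per voxel.
#' @slot stats list of stitching statistics (pairwise shifts, residuals,
#'   artifact fractions).
#' @export
setClass("StitchResult", representation(
  fused = "array",
  voxelSizeUm = "numeric",
  originMm = "numeric",
  stdMap = "array",
  provenance = "array",
  stats = "list"
), validity = function(object) {
  if (any(object@stdMap < 0)) return("stdMap must be >= 0")
  if (!identical(dim(object@fused), dim(object@stdMap)))
    return("stdMap shape must match fused volume")
  TRUE
})

#' Airway segmentation of a fused volume
#'
#' @slot airwayMask logical array labelling airway voxels.
#' @slot boneMask logical array labelling bone voxels.
#' @slot sliceThresholds per-slice iso-threshold values used in the final
#'   pass.
#' @slot volumeCm3 airway volume: voxel count times voxel volume, cm^3.
#' @slot voxelSizeUm voxel size, micrometres.
#' @export
setClass("SegmentationResult", representation(
  airwayMask = "array",
  boneMask = "array",
  sliceThresholds = "numeric",
  volumeCm3 = "numeric",
  voxelSizeUm = "numeric"
), validity = function(object) {
  if (any(object@airwayMask & object@boneMask))
    return("airway and bone masks must be disjoint")
  vox_cm3 <- (object@voxelSizeUm * 1e-4)^3
  if (abs(object@volumeCm3 - sum(object@airwayMask) * vox_cm3) >
      1e-9 * max(1, object@volumeCm3))
    return("volumeCm3 must equal mask count times voxel volume")
  TRUE
})
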