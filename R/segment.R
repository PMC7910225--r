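# Four-step airway segmentation: bone masking, slice-wise iso-thresholding,
# 3-D connectivity, and a refined second thresholding pass on a sharpened
# copy restricted to the dilated first-pass mask.

#' Global-threshold bone mask
#'
#' Bone shows much higher reconstructed attenuation than soft tissue and is
#' rejected with one global threshold before airway thresholding.
#'
#' @param vol reconstructed volume (array).
#' @param globalThreshold attenuation threshold.
#' @return logical array: \code{vol > globalThreshold}.
#' @export
maskBone <- function(vol, globalThreshold) {
  m <- vol > globalThreshold
  if (all(m)) message("bone threshold below the volume minimum: full mask")
  m
}

# Ridler-Calvard iterative intermeans threshold of a numeric vector.
intermeansThreshold <- function(v, tol = 1e-6, maxIter = 200) {
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2) return(NA_real_)
  t0 <- mean(v)
  for (i in seq_len(maxIter)) {
    lo <- v[v <= t0]; hi <- v[v > t0]
    if (!length(lo) || !length(hi)) return(t0)
    t1 <- (mean(lo) + mean(hi)) / 2
    if (abs(t1 - t0) < tol) return(t1)
    t0 <- t1
  }
  t0
}

#' Cylindrical mask roughly bounding the lung
#'
#' Auto-fits a cylinder to the body outline: the body is taken as the voxels
#' above the global air/tissue intermeans threshold, and the cylinder is
#' centred on their centroid with radius \code{frac} times the equivalent
#' body radius.
#'
#' @param vol reconstructed volume.
#' @param frac radius shrink factor.
#' @return logical array (constant over z).
#' @export
autoCylinderMask <- function(vol, frac = 0.95) {
  t1 <- intermeansThreshold(as.vector(vol))
  zmid <- ceiling(dim(vol)[3] / 2)
  sl <- vol[, , zmid] > t1
  if (!any(sl)) stop("no body found for the cylinder auto-fit")
  idx <- which(sl, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  r <- frac * sqrt(nrow(idx) / pi)
  xy <- outer((seq_len(dim(vol)[1]) - cx)^2,
              (seq_len(dim(vol)[2]) - cy)^2, "+") <= r^2
  array(rep(as.vector(xy), dim(vol)[3]), dim(vol))
}

#' Slice-wise iso-thresholding into air and tissue
#'
#' For every axial slice, an iterative intermeans (Ridler-Calvard) threshold
#' is computed over the pixels inside the cylinder mask and outside the
#' exclusion masks; pixels below the threshold are labelled air.  Degenerate
#' slices (fewer than two distinct values) borrow the nearest valid slice's
#' threshold with a warning.
#'
#' @param vol reconstructed volume.
#' @param exclusionMask logical array of pixels to exclude (e.g. bone), or
#'   NULL.
#' @param cylinderMask logical array bounding the lung, or NULL for all.
#' @return list: \code{mask} (logical array, air pixels inside the
#'   considered region) and \code{thresholds} (per-slice).
#' @export
isoThresholdSlicewise <- function(vol, exclusionMask = NULL,
                                  cylinderMask = NULL) {
  d <- dim(vol)
  consider <- array(TRUE, d)
  if (!is.null(cylinderMask)) consider <- consider & cylinderMask
  if (!is.null(exclusionMask)) consider <- consider & !exclusionMask
  thr <- rep(NA_real_, d[3])
  for (z in seq_len(d[3])) {
    v <- vol[, , z][consider[, , z]]
    thr[z] <- intermeansThreshold(v)
  }
  if (anyNA(thr)) {
    if (all(is.na(thr))) stop("no slice has two distinct values")
    warning(sprintf("%d degenerate slices; borrowing nearest thresholds",
                    sum(is.na(thr))))
    ok <- which(!is.na(thr))
    for (z in which(is.na(thr))) thr[z] <- thr[ok[which.min(abs(ok - z))]]
  }
  mask <- array(FALSE, d)
  for (z in seq_len(d[3]))
    mask[, , z] <- vol[, , z] < thr[z] & consider[, , z]
  list(mask = mask, thresholds = thr)
}

#' Retain the 3-D connected airway component
#'
#' Keeps only the air voxels 26-connected to the trachea seed region: by
#' default the largest component touching the top face (highest z slice).
#' If no component touches the seed region, the largest component overall is
#' retained with a warning.
#'
#' @param mask logical array of candidate air voxels.
#' @return logical array: the retained airway component.
#' @export
extractConnectedAirways <- function(mask) {
  if (!any(mask)) stop("empty air mask")
  lab <- conncomp3d_cpp(mask)
  sizes <- tabulate(lab[lab > 0])
  topLabs <- unique(as.vector(lab[, , dim(mask)[3]]))
  topLabs <- topLabs[topLabs > 0]
  keep <- if (length(topLabs)) topLabs[which.max(sizes[topLabs])] else {
    warning("no component touches the top face; keeping the largest")
    which.max(sizes)
  }
  out <- lab == keep
  dim(out) <- dim(mask)
  out
}

#' Refined second-pass segmentation and volume quantification
#'
#' Dilates the first-pass airway mask (ensuring air plus adjacent tissue
#' pixels are used), re-runs the slice-wise intermeans thresholding on an
#' unsharp-masked copy of the volume restricted to the dilated region, and
#' reports the final airway volume.
#'
#' @param vol reconstructed volume.
#' @param airwayMask first-pass airway mask.
#' @param dilationRadius dilation ball radius, voxels.
#' @param sharpnessAmount unsharp-mask amount (0 = plain second pass).
#' @param sharpnessSigma Gaussian sigma of the unsharp mask, pixels.
#' @param voxelSizeUm voxel size for the volume report.
#' @return list: \code{mask}, \code{thresholds}, \code{volume_cm3}.
#' @export
refineSegmentation <- function(vol, airwayMask, dilationRadius = 3,
                               sharpnessAmount = 1.0, sharpnessSigma = 2,
                               voxelSizeUm = 2.75) {
  stopifnot(any(airwayMask))
  dil <- dilate3d_cpp(airwayMask, dilationRadius)
  sharp <- vol
  if (sharpnessAmount > 0) {
    for (z in seq_len(dim(vol)[3])) {
      sl <- vol[, , z]
      sharp[, , z] <- sl + sharpnessAmount *
        (sl - gaussSmooth2d(sl, sharpnessSigma))
    }
  }
  second <- isoThresholdSlicewise(sharp, exclusionMask = !dil)
  mask <- second$mask & dil
  list(mask = mask, thresholds = second$thresholds,
       volume_cm3 = sum(mask) * (voxelSizeUm * 1e-4)^3)
}

#' Full four-step airway segmentation
#'
#' Chains \code{\link{maskBone}}, \code{\link{isoThresholdSlicewise}} (with a
#' cylindrical lung mask), \code{\link{extractConnectedAirways}} and
#' \code{\link{refineSegmentation}}.
#'
#' @param x a \linkS4class{StitchResult} or a reconstructed array.
#' @param boneThreshold global bone threshold; NULL auto-derives it as the
#'   intermeans split of the above-tissue values (two-stage intermeans).
#' @param cylinderMask logical array, or NULL for \code{\link{autoCylinderMask}}.
#' @param dilationRadius,sharpnessAmount,sharpnessSigma see
#'   \code{\link{refineSegmentation}}.
#' @param voxelSizeUm voxel size; taken from \code{x} when available.
#' @return A \linkS4class{SegmentationResult}.
#' @export
segmentAirways <- function(x, boneThreshold = NULL, cylinderMask = NULL,
                           dilationRadius = 3, sharpnessAmount = 1.0,
                           sharpnessSigma = 2, voxelSizeUm = NULL) {
  if (is(x, "StitchResult")) {
    vol <- x@fused
    if (is.null(voxelSizeUm)) voxelSizeUm <- x@voxelSizeUm
  } else {
    vol <- x
    if (is.null(voxelSizeUm)) stop("voxelSizeUm required for bare arrays")
  }
  if (is.null(boneThreshold)) {
    t1 <- intermeansThreshold(as.vector(vol))
    boneThreshold <- intermeansThreshold(vol[vol > t1])
  }
  bone <- maskBone(vol, boneThreshold)
  if (is.null(cylinderMask)) cylinderMask <- autoCylinderMask(vol)
  first <- isoThresholdSlicewise(vol, exclusionMask = bone,
                                 cylinderMask = cylinderMask)
  air <- extractConnectedAirways(first$mask)
  ref <- refineSegmentation(vol, air, dilationRadius = dilationRadius,
                            sharpnessAmount = sharpnessAmount,
                            sharpnessSigma = sharpnessSigma,
                            voxelSizeUm = voxelSizeUm)
  mask <- ref$mask & !bone
  new("SegmentationResult", airwayMask = mask, boneMask = bone,
      sliceThresholds = ref$thresholds,
      volumeCm3 = sum(mask) * (voxelSizeUm * 1e-4)^3,
      voxelSizeUm = voxelSizeUm)
}

#' Airway volume of a segmentation
#' @param seg a \linkS4class{SegmentationResult}.
#' @return volume in cm^3.
#' @export
airwayVolumeCm3 <- function(seg) seg@volumeCm3

setMethod("show", "SegmentationResult", function(object) {
  d <- dim(object@airwayMask)
  cat(sprintf("SegmentationResult: %d x %d x %d voxels at %.3g um\n",
              d[1], d[2], d[3], object@voxelSizeUm))
  cat(sprintf("  airway volume %.4g cm^3 (%d voxels); bone voxels %d\n",
              object@volumeCm3, sum(object@airwayMask),
              sum(object@boneMask)))
})
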