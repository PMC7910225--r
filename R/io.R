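# On-disk containers.
#
# A projection set is a directory with float64 raw blocks plus meta.json:
#   data.raw, data_dark.raw, data_white.raw   (little-endian float64)
#   meta.json: dims of each block, theta (degrees), pixel_size_um,
#              timestamp_s, grid_index, axis_offset_px, eps_deg
# This mirrors the usual tomography exchange layout (projections, darks,
# whites, angles, attributes) in a dependency-free container with a lossless
# round trip.
#
# Tile volumes and fused volumes are written as 32-bit TIFF stacks (one page
# per z slice, values min/max-normalized) with a JSON sidecar carrying the
# scale, origin_mm, voxel size, tile index and timestamp.

writeRawBlock <- function(arr, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(arr), con, size = 8, endian = "little")
}

readRawBlock <- function(path, dims) {
  con <- file(path, "rb")
  on.exit(close(con))
  array(readBin(con, "numeric", n = prod(dims), size = 8,
                endian = "little"), dims)
}

#' Write a projection set to disk
#'
#' @param ps a \linkS4class{ProjectionSet}.
#' @param path directory to create/overwrite.
#' @return \code{path}, invisibly.
#' @export
writeProjectionSet <- function(ps, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  writeRawBlock(ps@data, file.path(path, "data.raw"))
  writeRawBlock(ps@darks, file.path(path, "data_dark.raw"))
  writeRawBlock(ps@flats, file.path(path, "data_white.raw"))
  meta <- list(
    data_dims = dim(ps@data), dark_dims = dim(ps@darks),
    white_dims = dim(ps@flats), theta = ps@thetaDeg,
    pixel_size_um = ps@pixelSizeUm, timestamp_s = ps@timestampS,
    grid_index = ps@gridIndex, axis_offset_px = ps@axisOffsetPx,
    eps_deg = ps@epsDeg)
  jsonlite::write_json(meta, file.path(path, "meta.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a projection set from disk
#'
#' Missing blocks or metadata members raise an explicit schema error naming
#' the offending path.
#'
#' @param path directory written by \code{\link{writeProjectionSet}}.
#' @return A \linkS4class{ProjectionSet}.
#' @export
readProjectionSet <- function(path) {
  metaPath <- file.path(path, "meta.json")
  if (!file.exists(metaPath))
    stop(sprintf("schema error: missing %s", metaPath))
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  need <- c("data_dims", "dark_dims", "white_dims", "theta",
            "pixel_size_um", "timestamp_s", "grid_index", "axis_offset_px")
  for (m in need)
    if (is.null(meta[[m]]))
      stop(sprintf("schema error: missing member '%s' in %s", m, metaPath))
  for (f in c("data.raw", "data_dark.raw", "data_white.raw"))
    if (!file.exists(file.path(path, f)))
      stop(sprintf("schema error: missing %s", file.path(path, f)))
  new("ProjectionSet",
      data = readRawBlock(file.path(path, "data.raw"), meta$data_dims),
      darks = readRawBlock(file.path(path, "data_dark.raw"), meta$dark_dims),
      flats = readRawBlock(file.path(path, "data_white.raw"),
                           meta$white_dims),
      thetaDeg = as.numeric(meta$theta),
      pixelSizeUm = meta$pixel_size_um, timestampS = meta$timestamp_s,
      gridIndex = as.integer(meta$grid_index),
      axisOffsetPx = meta$axis_offset_px,
      epsDeg = if (is.null(meta$eps_deg)) 0 else meta$eps_deg)
}

#' Write a tile volume as a 32-bit TIFF stack with a JSON sidecar
#'
#' @param tile a \linkS4class{TileVolume}.
#' @param path output path without extension; writes \code{path.tif} and
#'   \code{path.json}.
#' @return \code{path}, invisibly.
#' @export
writeTileVolume <- function(tile, path) {
  v <- tile@vol
  lo <- min(v); hi <- max(v)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(v)[3]), function(z)
    (v[, , z] - lo) / scale)
  tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 32,
                  reduce = FALSE)
  meta <- list(dims = dim(v), value_min = lo, value_scale = scale,
               voxel_size_um = tile@voxelSizeUm, origin_mm = tile@originMm,
               grid_index = tile@gridIndex, timestamp_s = tile@timestampS)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a tile volume written by \code{\link{writeTileVolume}}
#' @param path path without extension.
#' @return A \linkS4class{TileVolume}.
#' @export
readTileVolume <- function(path) {
  jp <- paste0(path, ".json")
  if (!file.exists(jp)) stop(sprintf("schema error: missing %s", jp))
  meta <- jsonlite::read_json(jp, simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  v <- array(0, meta$dims)
  for (z in seq_along(pages))
    v[, , z] <- meta$value_min + pages[[z]] * meta$value_scale
  new("TileVolume", vol = v, voxelSizeUm = meta$voxel_size_um,
      originMm = as.numeric(meta$origin_mm),
      gridIndex = as.integer(meta$grid_index),
      timestampS = meta$timestamp_s)
}

#' Default pipeline configuration
#'
#' One nested list holding every stage's parameters; serializes losslessly
#' through YAML.  The default describes a desk-scale smoke run: a 2 x 1 x 2
#' mosaic of extended-FOV tiles over a foam phantom.
#'
#' @param seed master seed.
#' @return named list (a pipeline configuration).
#' @export
defaultPipelineConfig <- function(seed = 1) {
  list(
    seed = seed,
    optics = list(energy_keV = 21, propagation_distance_m = 0.1,
                  pixel_size_um = 2.75, delta = 2.0e-7, beta = 2.8e-10),
    plan = list(grid_shape = c(2, 2, 2),
                tile_extent_mm = c(0.572, 0.572, 0.132),
                step_mm = c(0.352, 0.099), pixel_size_um = 2.75),
    phantom = list(shape_vox = c(340, 340, 88), target_air_fraction = 0.25,
                   wall_thickness_um = 22, body_radius_frac = 0.265,
                   lung_radius_frac = 0.21, mu_tissue = 2800),
    simulate = list(n_proj = 240, detector_width_px = 128,
                    axis_offset_px = 24, eps_deg = 0.04565, n_dark = 20,
                    n_flat = 60, illum_K = 3, illum_rel_amplitude = 0.02,
                    deform_rate_vox_s = 0.0, noise = TRUE),
    preprocess = list(method = "static", K = 3, margin_cols = 8),
    reconstruct = list(overlap_mode = "cut", apodization = "ramlak"),
    stitch = list(grid_spacing_vox = 16, block_radius_vox = 6,
                  search_radius_vox = 4, score_threshold = 0.3,
                  max_displacement_vox = 10, ramp_vox = 6,
                  std_threshold = 15),
    segment = list(dilation_radius = 3, sharpness_amount = 1.0,
                   sharpness_sigma = 2)
  )
}

#' Read / write a pipeline configuration
#' @param path YAML file path.
#' @param config configuration list.
#' @return \code{readPipelineConfig}: the configuration list.
#' @export
readPipelineConfig <- function(path) yaml::read_yaml(path)

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
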