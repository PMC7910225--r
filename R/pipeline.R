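#' Run the full mosaic pipeline on a configuration
#'
#' Executes simulate -> preprocess/retrieve/reconstruct (per tile) -> stitch
#' -> segment from one configuration list (see
#' \code{\link{defaultPipelineConfig}}), logging per-stage timings.  All
#' randomness is funnelled through the configuration's seed, so identical
#' configurations give identical results.
#'
#' @param config configuration list.
#' @param workDir if non-NULL, tile projection sets and volumes are written
#'   there.
#' @param verbose print stage progress.
#' @return list: \code{phantom}, \code{plan}, \code{tiles} (reconstructed
#'   \linkS4class{TileVolume}s), \code{stitch} (\linkS4class{StitchResult}),
#'   \code{segmentation} (\linkS4class{SegmentationResult}) and
#'   \code{report} (timings, parameters, summary metrics).
#' @export
runPipeline <- function(config = defaultPipelineConfig(), workDir = NULL,
                        verbose = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(sprintf(...))

  optics <- OpticsConfig(
    energyKeV = config$optics$energy_keV,
    propagationDistanceM = config$optics$propagation_distance_m,
    pixelSizeUm = config$optics$pixel_size_um,
    delta = config$optics$delta, beta = config$optics$beta)
  plan <- buildPlan(config$plan$grid_shape, config$plan$tile_extent_mm,
                    config$plan$step_mm, config$plan$pixel_size_um)

  say("phantom: %s voxels", paste(config$phantom$shape_vox, collapse = "x"))
  s <- tic()
  phantom <- makeFoamPhantom(config$phantom$shape_vox,
                             voxelSizeUm = config$plan$pixel_size_um,
                             targetAirFraction =
                               config$phantom$target_air_fraction,
                             wallThicknessUm =
                               config$phantom$wall_thickness_um,
                             bodyRadiusFrac =
                               config$phantom$body_radius_frac %||% 0.47,
                             lungRadiusFrac =
                               config$phantom$lung_radius_frac %||% 0.38,
                             muTissue = config$phantom$mu_tissue %||% 55,
                             seed = config$seed)
  timings$phantom <- tic() - s

  sim <- config$simulate
  zRows <- round(config$plan$tile_extent_mm[3] /
                   (config$plan$pixel_size_um * 1e-3))
  illum <- makeIlluminationModel(c(zRows + 4L, sim$detector_width_px),
                                 K = sim$illum_K,
                                 relAmplitude = sim$illum_rel_amplitude,
                                 seed = config$seed)
  deform <- if (sim$deform_rate_vox_s > 0)
    makeDeformationModel(dim(phantom@vol),
                         ratePerS = sim$deform_rate_vox_s,
                         seed = config$seed) else NULL

  say("simulate: %d tiles x %d projections", nTiles(plan), sim$n_proj)
  s <- tic()
  sets <- simulateMosaic(phantom, plan, optics, illum, deform = deform,
                         nProj = sim$n_proj, seed = config$seed,
                         detectorWidthPx = sim$detector_width_px,
                         axisOffsetPx = sim$axis_offset_px,
                         epsDeg = sim$eps_deg, nDark = sim$n_dark,
                         nFlat = sim$n_flat, noise = sim$noise,
                         dir = if (is.null(workDir)) NULL else
                           file.path(workDir, "projections"))
  timings$simulate <- tic() - s

  say("reconstruct: %d tiles", length(sets))
  s <- tic()
  tiles <- lapply(sets, function(ps)
    reconstructTile(ps, plan, optics,
                    correction = config$preprocess$method,
                    K = config$preprocess$K,
                    overlapMode = config$reconstruct$overlap_mode,
                    apodization = config$reconstruct$apodization))
  timings$reconstruct <- tic() - s
  if (!is.null(workDir)) {
    vd <- file.path(workDir, "tiles")
    if (!dir.exists(vd)) dir.create(vd, recursive = TRUE)
    for (i in seq_along(tiles))
      writeTileVolume(tiles[[i]], file.path(vd, sprintf("tile_%03d", i - 1)))
  }

  say("stitch: %d tiles", length(tiles))
  s <- tic()
  stcfg <- config$stitch
  stitch <- stitchMosaic(tiles, nonRigid = TRUE,
                         gridSpacingVox = stcfg$grid_spacing_vox,
                         blockRadiusVox = stcfg$block_radius_vox,
                         searchRadiusVox = stcfg$search_radius_vox,
                         scoreThreshold = stcfg$score_threshold,
                         maxDisplacementVox = stcfg$max_displacement_vox,
                         rampVox = stcfg$ramp_vox,
                         stdThreshold = stcfg$std_threshold)
  timings$stitch <- tic() - s

  say("segment")
  s <- tic()
  seg <- segmentAirways(stitch,
                        dilationRadius = config$segment$dilation_radius,
                        sharpnessAmount = config$segment$sharpness_amount,
                        sharpnessSigma = config$segment$sharpness_sigma)
  timings$segment <- tic() - s

  ov <- stitch@provenance >= 2L
  report <- list(
    config = config,
    config_checksum = configChecksum(config),
    timings_s = timings,
    total_s = tic() - t0,
    duration_prediction = estimateDuration(plan),
    overlap_std_mean = mean(stitch@stdMap[ov]),
    artifact_stats = stitch@stats$artifacts,
    airway_volume_cm3 = seg@volumeCm3,
    phantom_air_volume_mm3 = phantom@airVolumeMm3)
  if (!is.null(workDir))
    jsonlite::write_json(report[c("config_checksum", "timings_s", "total_s",
                                  "overlap_std_mean", "airway_volume_cm3",
                                  "phantom_air_volume_mm3")],
                         file.path(workDir, "report.json"), digits = NA,
                         auto_unbox = TRUE)
  list(phantom = phantom, plan = plan, sets = sets, tiles = tiles,
       stitch = stitch, segmentation = seg, report = report)
}

# cheap deterministic checksum of a configuration (provenance tagging)
configChecksum <- function(config) {
  s <- yaml::as.yaml(config)
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 251)) %% 4294967291)
}
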