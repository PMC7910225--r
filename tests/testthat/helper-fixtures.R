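# Shared fixtures, built once per test run and cached across test files.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# small foam phantom used by phantom/segmentation tests
foamSmall <- function() fixture("foamSmall", function() {
  makeFoamPhantom(c(160, 160, 160), 2.75, 0.6, seed = 11)
})

# airway-scale phantom (features well above the retrieval PSF) + noisy copy
airwayPhantom <- function() fixture("airwayPhantom", function() {
  ph <- makeFoamPhantom(c(220, 220, 110), 2.75, 0.25, wallThicknessUm = 30,
                        bodyRadiusFrac = 0.40, lungRadiusFrac = 0.32,
                        muTissue = 2800, seed = 3)
  set.seed(9)
  noisy <- ph@vol + array(rnorm(length(ph@vol), sd = 0.03 * 2800),
                          dim(ph@vol))
  list(phantom = ph, noisy = noisy)
})

# drifting-illumination scan of a smooth radially symmetric phantom with
# clean detector margins: the dynamic-vs-static comparison scenario
driftScan <- function() fixture("driftScan", function() {
  optics <- OpticsConfig()
  n <- 96; W <- 128; nproj <- 180
  r2 <- outer((1:n - 48.5)^2, (1:n - 48.5)^2, "+")
  ph <- array(rep(2800 * exp(-r2 / (2 * 16^2)), 8), c(n, n, 8))
  ang <- seq(0, 180, length.out = nproj + 1)[1:nproj]
  depth <- projectParallel(ph, ang, axisOffsetPx = 63.5,
                           detectorWidthPx = W, voxelSizeUm = 2.75)
  illum <- makeIlluminationModel(c(8, W), K = 3, relAmplitude = 0.03,
                                 ar1 = 0.9, seed = 4)
  co <- illumCoefficients(illum, nproj, seed = 5)
  raw <- array(0, c(nproj, 8, W))
  for (i in seq_len(nproj))
    raw[i, , ] <- applyContrastAndIllumination(
      matrix(depth[i, , ], 8, W), optics, illum, coefs = co[i, ],
      noise = TRUE, noiseSeed = 1000 + i)
  set.seed(77)
  darks <- array(rep(illum@darkMean, each = 30), c(30, 8, W))
  fco <- illumCoefficients(illum, 120, seed = 6)
  flats <- array(0, c(120, 8, W))
  for (i in 1:120)
    flats[i, , ] <- matrix(rpois(8 * W, pmax(flatAtInternal(illum, fco[i, ]),
                                             0)), 8) + illum@darkMean
  ps <- new("ProjectionSet", data = raw, darks = darks, flats = flats,
            thetaDeg = ang, pixelSizeUm = 2.75, timestampS = 0,
            gridIndex = c(0L, 0L, 0L), axisOffsetPx = 63.5, epsDeg = 0)
  list(ps = ps, illum = illum, angles = ang, optics = optics)
})

flatAtInternal <- function(illum, coefs) {
  f <- illum@meanFlat
  K <- nComponents(illum)
  if (K > 0) for (k in seq_len(K)) f <- f + coefs[k] * illum@components[, , k]
  f
}

# corrected sinograms and reconstructed slices for both flat-field methods
driftCorrected <- function() fixture("driftCorrected", function() {
  sc <- driftScan()
  tS <- correctProjections(sc$ps, "static")
  tD <- correctProjections(sc$ps, "dynamic", K = 3, marginCols = 20)
  sS <- matrix(tS[, 4, ], dim(tS)[1], dim(tS)[3])
  sD <- matrix(tD[, 4, ], dim(tD)[1], dim(tD)[3])
  rS <- fbpSlice(-log(pmax(sS, 1e-6)), sc$angles, centerPx = 63.5,
                 pixelSizeUm = 2.75)
  rD <- fbpSlice(-log(pmax(sD, 1e-6)), sc$angles, centerPx = 63.5,
                 pixelSizeUm = 2.75)
  list(sS = sS, sD = sD, rS = rS, rD = rD)
})

# extended-FOV scene: phantom wider than half the detector, 360-degree scan
# with the complementary-pair offset, plus the 180-degree full-FOV oracle
extFovScene <- function() fixture("extFovScene", function() {
  n <- 208; W <- 128; cpx <- 24
  cx <- (n + 1) / 2
  disc <- function(cx0, cy0, R, a) {
    r <- sqrt(outer((1:n - cx0)^2, (1:n - cy0)^2, "+"))
    a * pmin(1, pmax(0, R - r + 0.5))
  }
  phs <- disc(cx, cx, 95, 20) + disc(cx - 40, cx + 20, 25, 30) +
    disc(cx + 35, cx - 30, 18, 40)
  vol <- array(phs, c(n, n, 1))
  nproj <- 720
  eps <- 0.04565
  nominal <- seq(0, 360, length.out = nproj + 1)[1:nproj]
  theta <- nominal + ifelse(nominal >= 180, eps, 0)
  sino <- projectParallel(vol, theta, axisOffsetPx = cpx,
                          detectorWidthPx = W, voxelSizeUm = 2.75)
  angO <- seq(0, 180, length.out = 361)[1:360]
  sinoO <- projectParallel(vol, angO, voxelSizeUm = 2.75)
  mask <- outer((1:n - cx)^2, (1:n - cx)^2, "+") <= 100^2
  list(truth = phs, mask = mask, n = n, W = W, cpx = cpx, eps = eps,
       nominal = nominal, sino = matrix(sino[, 1, ], nproj, W),
       sinoO = matrix(sinoO[, 1, ], 360, n), angO = angO)
})

# deformed two-tile pair for non-rigid stitching tests
deformedPair <- function() fixture("deformedPair", function() {
  ph <- makeFoamPhantom(c(260, 150, 120), 2.75, 0.25, wallThicknessUm = 22,
                        bodyRadiusFrac = 0.45, lungRadiusFrac = 0.36,
                        muTissue = 2800, seed = 7)
  set.seed(5)
  # textured surroundings (chest tissue) so local matching is well posed
  # everywhere in the overlap, plus detector-like noise
  tex <- mosaicCT:::gaussSmooth3d(array(rnorm(length(ph@vol)),
                                        dim(ph@vol)), 3)
  vol <- ph@vol + tex * (150 / sd(tex)) +
    array(rnorm(length(ph@vol), sd = 30), dim(ph@vol))
  dm <- makeDeformationModel(dim(vol), controlPoints = 5, ratePerS = 0.08,
                             seed = 8)
  vox <- 2.75e-3
  mk <- function(xr, zr, t) {
    d <- c(length(xr), 150, length(zr))
    g <- expand.grid(x = xr, y = 1:150, z = zr)
    u <- deformationAt(dm, t, g$x, g$y, g$z)
    v <- array(mosaicCT:::sample_trilinear_cpp(
      vol, g$x - 1 + u[, 1], g$y - 1 + u[, 2], g$z - 1 + u[, 3], 0), d)
    new("TileVolume", vol = v, voxelSizeUm = 2.75,
        originMm = c(xr[1] - 1, 0, zr[1] - 1) * vox,
        gridIndex = c(0L, 0L, 0L), timestampS = t)
  }
  list(tiles = list(mk(1:140, 1:120, 0), mk(121:260, 1:120, 60)),
       model = dm, vol = vol)
})

# generic textured volume warped by a known smooth field: the planted-field
# recovery scenario for block matching
plantedField <- function() fixture("plantedField", function() {
  d <- c(96, 96, 64)
  set.seed(11)
  A <- mosaicCT:::gaussSmooth3d(array(rnorm(prod(d)), d), 2)
  g <- expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3])
  ux <- 2 * sin(2 * pi * g$x / 96) * cos(2 * pi * g$y / 96)
  uy <- 2 * cos(2 * pi * g$y / 96) * sin(2 * pi * g$z / 64)
  uz <- 1.4 * sin(2 * pi * g$z / 64)
  B <- array(mosaicCT:::sample_trilinear_cpp(A, g$x - 1 - ux, g$y - 1 - uy,
                                             g$z - 1 - uz, 0), d)
  truthAt <- function(pts)
    cbind(2 * sin(2 * pi * pts[, 1] / 96) * cos(2 * pi * pts[, 2] / 96),
          2 * cos(2 * pi * pts[, 2] / 96) * sin(2 * pi * pts[, 3] / 64),
          1.4 * sin(2 * pi * pts[, 3] / 64))
  list(A = A, B = B, truthAt = truthAt)
})

# 2 x 1 x 2 deformed mosaic of tile volumes (no tomography)
deformedMosaic <- function() fixture("deformedMosaic", function() {
  ph <- makeFoamPhantom(c(260, 150, 120), 2.75, 0.25, wallThicknessUm = 22,
                        bodyRadiusFrac = 0.45, lungRadiusFrac = 0.36,
                        muTissue = 2800, seed = 7)
  set.seed(5)
  vol <- ph@vol + array(rnorm(length(ph@vol), sd = 30), dim(ph@vol))
  dm <- makeDeformationModel(dim(vol), controlPoints = 5, ratePerS = 0.08,
                             seed = 8)
  vox <- 2.75e-3
  mk <- function(xr, zr, t) {
    d <- c(length(xr), 150, length(zr))
    g <- expand.grid(x = xr, y = 1:150, z = zr)
    u <- deformationAt(dm, t, g$x, g$y, g$z)
    v <- array(mosaicCT:::sample_trilinear_cpp(
      vol, g$x - 1 + u[, 1], g$y - 1 + u[, 2], g$z - 1 + u[, 3], 0), d)
    new("TileVolume", vol = v, voxelSizeUm = 2.75,
        originMm = c(xr[1] - 1, 0, zr[1] - 1) * vox,
        gridIndex = c(0L, 0L, 0L), timestampS = t)
  }
  list(tiles = list(mk(1:140, 1:70, 0), mk(121:260, 1:70, 40),
                    mk(121:260, 51:120, 80), mk(1:140, 51:120, 120)),
       model = dm)
})

# full desk-scale pipeline run (the end-to-end fixture)
pipelineRun <- function() fixture("pipelineRun", function() {
  suppressWarnings(suppressMessages(
    runPipeline(defaultPipelineConfig(seed = 1), verbose = FALSE)))
})

# small mosaic simulation for structural/IO checks
miniMosaic <- function() fixture("miniMosaic", function() {
  plan <- buildPlan(c(2, 1, 2), c(0.286, 0.286, 0.066), c(0.22, 0.0495),
                    pixelSizeUm = 2.75)
  ph <- makeFoamPhantom(c(186, 106, 44), 2.75, 0.25, wallThicknessUm = 16,
                        bodyRadiusFrac = 0.40, lungRadiusFrac = 0.30,
                        muTissue = 2800, seed = 2)
  illum <- makeIlluminationModel(c(28, 64), K = 2, seed = 2)
  sets <- suppressMessages(simulateMosaic(
    ph, plan, OpticsConfig(), illum, deform = NULL, nProj = 24, seed = 2,
    detectorWidthPx = 64, axisOffsetPx = 12, epsDeg = 0.04565,
    nDark = 5, nFlat = 8, noise = TRUE))
  list(plan = plan, phantom = ph, sets = sets, illum = illum)
})
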