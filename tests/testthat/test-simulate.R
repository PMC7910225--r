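test_that("projector integrates chords exactly for a uniform cylinder", {
  n <- 64
  vol <- array(0, c(n, n, 2))
  r2 <- outer((1:n - 32.5)^2, (1:n - 32.5)^2, "+")
  mu0 <- 40
  vol[, , 1][r2 <= 20^2] <- mu0
  vol[, , 2] <- vol[, , 1]
  ang <- c(0, 45, 90, 170, 260)
  sino <- projectParallel(vol, ang, voxelSizeUm = 2.75)
  centre <- sino[, 1, 32]  # ray through the axis
  expect_equal(centre, rep(2 * 20 * 2.75e-6 * mu0, 5), tolerance = 0.02)
  expect_true(all(projectParallel(array(0, c(16, 16, 2)), ang,
                                  voxelSizeUm = 2.75) == 0))
})

test_that("projection conserves mass and is linear", {
  set.seed(2)
  taper <- exp(-outer((1:40 - 20.5)^2, (1:40 - 20.5)^2, "+") / (2 * 6^2))
  A <- mosaicCT:::gaussSmooth3d(array(runif(40^3), c(40, 40, 40)), 3) *
    array(taper, c(40, 40, 40))
  B <- mosaicCT:::gaussSmooth3d(array(runif(40^3), c(40, 40, 40)), 3) *
    array(taper, c(40, 40, 40))
  ang <- seq(0, 160, by = 20)
  pA <- projectParallel(A, ang, voxelSizeUm = 2.75)
  pB <- projectParallel(B, ang, voxelSizeUm = 2.75)
  pAB <- projectParallel(2.5 * A + B, ang, voxelSizeUm = 2.75)
  expect_equal(pAB, 2.5 * pA + pB, tolerance = 1e-10)
  # detector sums per angle equal the voxel mass within 0.5%
  vox <- 2.75e-6
  mass <- sum(A[, , 20]) * vox^2
  sums <- apply(pA[, 20, ], 1, sum) * vox
  expect_true(all(abs(sums - mass) / mass < 0.005))
})

test_that("contrast stage: flat response at zero depth, DC gain one", {
  optics <- OpticsConfig()
  illum <- makeIlluminationModel(c(24, 32), K = 2, seed = 1)
  fr <- applyContrastAndIllumination(matrix(0, 24, 32), optics, illum,
                                     coefs = c(0, 0), noise = FALSE)
  expect_equal(fr, illum@meanFlat + illum@darkMean, tolerance = 1e-9)
  # constant optical depth: the transfer leaves constants unchanged
  fr2 <- applyContrastAndIllumination(matrix(0.4, 24, 32), optics, illum,
                                      coefs = c(0, 0), noise = FALSE)
  expect_equal(fr2, exp(-0.4) * illum@meanFlat + illum@darkMean,
               tolerance = 1e-9)
})

test_that("simulated mosaic has the documented structure", {
  mm <- miniMosaic()
  sets <- mm$sets
  expect_length(sets, 4)
  starts <- planTiles(mm$plan)$predicted_start_s
  for (r in seq_along(sets)) {
    ps <- sets[[r]]
    expect_equal(dim(ps@data)[1], 24)
    expect_equal(dim(ps@darks)[1], 5)
    expect_equal(dim(ps@flats)[1], 8)
    expect_equal(ps@timestampS, starts[r])
    # complementary projections carry the configured extra offset
    th <- ps@thetaDeg
    nominal <- seq(0, 360, length.out = 25)[1:24]
    expect_equal(th - nominal, ifelse(nominal >= 180, 0.04565, 0))
  }
  expect_true(all(diff(vapply(sets, function(s) s@timestampS,
                              numeric(1))) > 0))
})

test_that("mosaic simulation is deterministic given the seed", {
  mm <- miniMosaic()
  again <- suppressMessages(simulateMosaic(
    mm$phantom, mm$plan, OpticsConfig(), mm$illum, deform = NULL,
    nProj = 24, seed = 2, detectorWidthPx = 64, axisOffsetPx = 12,
    epsDeg = 0.04565, nDark = 5, nFlat = 8, noise = TRUE))
  expect_identical(mm$sets[[2]]@data, again[[2]]@data)
  expect_identical(mm$sets[[3]]@flats, again[[3]]@flats)
})

test_that("a tile outside the phantom is refused", {
  mm <- miniMosaic()
  plan <- buildPlan(c(4, 1, 2), c(0.286, 0.286, 0.066), c(0.22, 0.0495))
  expect_error(suppressMessages(simulateMosaic(
    mm$phantom, plan, OpticsConfig(), mm$illum, nProj = 4, seed = 1,
    detectorWidthPx = 64, axisOffsetPx = 12)), "outside")
})
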