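discPhantom <- function(n, cx0, cy0, R, mu0 = 50) {
  r <- sqrt(outer((1:n - cx0)^2, (1:n - cy0)^2, "+"))
  mu0 * pmin(1, pmax(0, R - r + 0.5))
}

test_that("FBP reconstructs a uniform disc to within 5%", {
  n <- 96
  mu0 <- 50
  sl0 <- discPhantom(n, (n + 1) / 2, (n + 1) / 2, 30, mu0)
  vol <- array(sl0, c(n, n, 1))
  ang <- seq(0, 180, length.out = 181)[1:180]
  sino <- projectParallel(vol, ang, voxelSizeUm = 2.75)
  sl <- fbpSlice(matrix(sino[, 1, ], 180, n), ang, pixelSizeUm = 2.75)
  inside <- outer((1:n - (n + 1) / 2)^2, (1:n - (n + 1) / 2)^2, "+") <= 25^2
  expect_gt(mean(sl[inside]) / mu0, 0.95)
  expect_lt(mean(sl[inside]) / mu0, 1.05)
  expect_lt(sqrt(mean((sl - sl0)^2)) / mu0, 0.05)
  expect_equal(fbpSlice(matrix(0, 180, n), ang, pixelSizeUm = 2.75),
               matrix(0, n, n))
})

test_that("FBP is linear in the sinogram", {
  n <- 48
  ang <- seq(0, 180, length.out = 61)[1:60]
  set.seed(3)
  s1 <- matrix(rnorm(60 * n), 60, n)
  s2 <- matrix(rnorm(60 * n), 60, n)
  r <- fbpSlice(1.5 * s1 - 2 * s2, ang)
  expect_equal(r, 1.5 * fbpSlice(s1, ang) - 2 * fbpSlice(s2, ang),
               tolerance = 1e-10)
})

test_that("translating the phantom translates the reconstruction", {
  n <- 96
  mu0 <- 50
  blob <- function(cx0) array(mu0 * exp(-outer((1:n - cx0)^2,
                                                (1:n - 48)^2, "+") /
                                           (2 * 8^2)), c(n, n, 1))
  ang <- seq(0, 180, length.out = 181)[1:180]
  s <- 3
  sl <- fbpSlice(matrix(projectParallel(blob(45), ang,
                                        voxelSizeUm = 2.75)[, 1, ], 180, n),
                 ang, pixelSizeUm = 2.75)
  slB <- fbpSlice(matrix(projectParallel(blob(45 + s), ang,
                                         voxelSizeUm = 2.75)[, 1, ], 180, n),
                  ang, pixelSizeUm = 2.75)
  expect_lt(max(abs(slB[(1 + s):n, ] - sl[1:(n - s), ])) /
              diff(range(sl)), 0.01)
})

test_that("extended-FOV assembly matches the full-FOV oracle", {
  sc <- extFovScene()
  recE <- reconstructExtendedFov(sc$sino, sc$nominal, sc$cpx,
                                 epsDeg = sc$eps, pixelSizeUm = 2.75)
  expect_equal(dim(recE), c(208, 208))
  recO <- fbpSlice(sc$sinoO, sc$angO, pixelSizeUm = 2.75)
  rmse <- function(a) sqrt(mean((a[sc$mask] - sc$truth[sc$mask])^2))
  expect_lt(rmse(recE), 2 * rmse(recO))
  # ignoring the planted complementary-pair offset degrades the result
  recE0 <- reconstructExtendedFov(sc$sino, sc$nominal, sc$cpx,
                                  epsDeg = 0, pixelSizeUm = 2.75)
  expect_gt(rmse(recE0), rmse(recE))
  # the angular-weighting overlap mode stays within the same band
  recW <- reconstructExtendedFov(sc$sino, sc$nominal, sc$cpx,
                                 epsDeg = sc$eps, pixelSizeUm = 2.75,
                                 overlapMode = "weight")
  expect_lt(rmse(recW), 2 * rmse(recO))
})

test_that("extended-FOV geometry limits", {
  na <- 16; m <- 32
  sino <- matrix(0, na, m)
  ang <- seq(0, 360, length.out = na + 1)[1:na]
  out <- suppressWarnings(reconstructExtendedFov(sino, ang, 0))
  expect_equal(dim(out), c(2 * m, 2 * m))
  out2 <- suppressWarnings(reconstructExtendedFov(sino, ang, (m - 1) / 2))
  expect_equal(dim(out2)[1], round(2 * (m - (m - 1) / 2)))
  expect_error(reconstructExtendedFov(sino, ang, m + 3), "center")
})

test_that("center search recovers a planted rotation axis within 0.5 px", {
  n <- 96; W <- 128
  r2 <- outer((1:n - 48.5)^2, (1:n - 48.5)^2, "+")
  ph <- array(2800 * exp(-r2 / (2 * 16^2)) *
                (1 + 0.3 * sin(outer(1:n, 1:n, "+") / 6)), c(n, n, 1))
  ang <- seq(0, 180, length.out = 121)[1:120]
  ctrue <- 60
  sino <- matrix(projectParallel(ph, ang, axisOffsetPx = ctrue,
                                 detectorWidthPx = W,
                                 voxelSizeUm = 2.75)[, 1, ], 120, W)
  fc <- findCenter(sino, ang, c(55, 65), stepPx = 0.5, pixelSizeUm = 2.75)
  expect_lt(abs(fc$center_px - ctrue), 0.5)
  expect_false(fc$at_edge)
  # score curve is symmetric about the true center for a symmetric object
  phs <- array(2800 * exp(-r2 / (2 * 16^2)), c(n, n, 1))
  sinos <- matrix(projectParallel(phs, ang, axisOffsetPx = ctrue,
                                  detectorWidthPx = W,
                                  voxelSizeUm = 2.75)[, 1, ], 120, W)
  fcs <- findCenter(sinos, ang, c(56, 64), stepPx = 1, pixelSizeUm = 2.75)
  sc <- fcs$scores
  expect_lt(max(abs(sc - rev(sc))), 0.15 * diff(range(sc)))
  # a range excluding the true center is flagged at-edge
  fce <- findCenter(sino, ang, c(50, 56), stepPx = 1, pixelSizeUm = 2.75)
  expect_true(fce$at_edge)
})

test_that("per-layer centers interpolate linearly", {
  expect_equal(interpolateCenters(100, 106, 7), seq(100, 106))
  expect_equal(interpolateCenters(101.5, 101.5, 5), rep(101.5, 5))
  expect_equal(interpolateCenters(100, 106, 2), c(100, 106))
})
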