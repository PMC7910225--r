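smoothNoiseVol <- function(dims, seed = 7, sigma = 1.5) {
  set.seed(seed)
  mosaicCT:::gaussSmooth3d(array(rnorm(prod(dims)), dims), sigma)
}

test_that("phase correlation refines a planted rigid offset", {
  A <- smoothNoiseVol(c(64, 64, 48))
  s <- c(3, -2, 5)
  B <- array(0, dim(A))
  B[4:64, 1:62, 6:48] <- A[1:61, 3:64, 1:43]  # B(x) = A(x - s)
  cs <- coarsePairwiseShift(A, B, c(0, 0, 0), searchRadiusVox = 8)
  # content shifted by +s aligns when B's origin moves by -s
  expect_equal(cs$offset, -s, tolerance = 0.2)
  expect_false(cs$low_confidence)
  # identical tiles: zero offset, near-perfect score
  cs2 <- coarsePairwiseShift(A, A, c(0, 0, 0), searchRadiusVox = 8)
  expect_equal(cs2$offset, c(0, 0, 0), tolerance = 1e-6)
  expect_gt(cs2$score, 0.99)
  # pure noise: low confidence, nominal kept
  set.seed(1)
  N1 <- array(rnorm(64 * 64 * 48), c(64, 64, 48))
  N2 <- array(rnorm(64 * 64 * 48), c(64, 64, 48))
  expect_warning(cs3 <- coarsePairwiseShift(N1, N2, c(0, 0, 0)),
                 "below threshold")
  expect_true(cs3$low_confidence)
  expect_equal(cs3$offset, c(0, 0, 0))
})

test_that("block matching recovers a planted smooth deformation field", {
  pf <- plantedField()
  f <- blockMatchField(pf$A, pf$B, c(0, 0, 0), gridSpacingVox = 16,
                       blockRadiusVox = 8, searchRadiusVox = 6)
  pu <- pf$truthAt(f@points)
  err <- sqrt(rowSums((f@shifts - pu)^2))
  expect_gt(sum(f@valid), 10)
  expect_lt(mean(err[f@valid]), 0.5)
  # zero deformation: the field equals the rigid shift everywhere
  f0 <- blockMatchField(pf$A, pf$A, c(0, 0, 0), gridSpacingVox = 24,
                        blockRadiusVox = 8, searchRadiusVox = 4)
  expect_lt(max(abs(f0@shifts[f0@valid, ])), 0.05)
  A <- pf$A
  # block radius larger than the overlap: all points invalid, warning
  expect_warning(
    fbad <- blockMatchField(A[1:20, , ], A[1:20, , ], c(0, 0, 0),
                            blockRadiusVox = 30, searchRadiusVox = 2),
    "no valid control points")
  expect_false(any(fbad@valid))
})

test_that("field filtering removes outliers and bounds gradients", {
  pts <- as.matrix(expand.grid(x = seq(10, 80, 14), y = seq(10, 80, 14),
                               z = 20))
  n <- nrow(pts)
  sh <- matrix(rep(c(2, -1, 0.5), each = n), n, 3)
  f <- new("DisplacementField", points = pts, shifts = sh,
           valid = rep(TRUE, n), scores = rep(0.9, n), spacingVox = 14)
  # constant fields are preserved
  fs <- filterAndSmoothField(f)
  expect_equal(fs@shifts, sh, tolerance = 1e-10)
  # a planted outlier is removed and repaired from its neighbours
  f2 <- f
  f2@shifts[5, ] <- f2@shifts[5, ] + c(25, 0, 0)
  fs2 <- filterAndSmoothField(f2)
  expect_lt(max(abs(fs2@shifts[5, ] - sh[5, ])), 1)
  # alternating spikes are smoothed below a gradient bound
  f3 <- f
  f3@shifts[, 1] <- f3@shifts[, 1] + 3 * (-1)^(seq_len(n))
  fs3 <- filterAndSmoothField(f3, madK = 50)
  gaps <- abs(diff(fs3@shifts[order(pts[, 1], pts[, 2]), 1]))
  expect_lt(max(gaps), 1.5)
  # everything invalid: identity field with the supplied fallback
  f4 <- f
  f4@valid[] <- FALSE
  expect_warning(fs4 <- filterAndSmoothField(f4, fallbackShift = c(1, 2, 3)),
                 "identity")
  expect_true(all(t(fs4@shifts) == c(1, 2, 3)))
})

test_that("global positioning solves consistent and inconsistent graphs", {
  nom <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0))
  # consistent triangle: exactly solvable
  pairs <- data.frame(a = c(1, 1, 2), b = c(2, 3, 3),
                      dx = c(101, 1, -100), dy = c(0, 99, 99),
                      dz = c(0, 0, 0), confidence = c(1, 1, 1))
  o <- globallyPositionTiles(pairs, nom)
  expect_equal(o[2, ] - o[1, ], c(101, 0, 0), tolerance = 1e-9)
  expect_equal(o[3, ] - o[1, ], c(1, 99, 0), tolerance = 1e-9)
  expect_equal(o[1, ], nom[1, ])  # anchored
  # the residual concentrates on the low-confidence edge
  pairs2 <- pairs
  pairs2$dx[3] <- -90   # inconsistent measurement
  pairs2$confidence <- c(10, 10, 0.1)
  o2 <- globallyPositionTiles(pairs2, nom)
  res <- c(sum(abs(o2[2, ] - o2[1, ] - c(101, 0, 0))),
           sum(abs(o2[3, ] - o2[1, ] - c(1, 99, 0))),
           sum(abs(o2[3, ] - o2[2, ] - c(-90, 99, 0))))
  expect_lt(res[1], 0.5)
  expect_lt(res[2], 0.5)
  expect_gt(res[3], 5)
  # single tile: nominal origin
  expect_equal(globallyPositionTiles(pairs[0, ], nom[1, , drop = FALSE]),
               nom[1, , drop = FALSE])
})

test_that("blending conserves constants and reports overlap std", {
  tA <- array(5, c(20, 20, 10))
  tB <- array(5, c(20, 20, 10))
  org <- rbind(c(0, 0, 0), c(10, 0, 0))
  st <- blendMosaic(list(tA, tB), org, rampVox = 3)
  cov <- st@provenance > 0
  expect_true(all(abs(st@fused[cov] - 5) < 1e-9))
  expect_true(all(st@stdMap == 0))
  expect_true(all(st@provenance[11:20, , ] >= 1L))
  # two tiles differing by d in the overlap: population std d/2
  st2 <- blendMosaic(list(tA, tA + 4), org, rampVox = 3)
  ov <- st2@provenance >= 2L
  expect_true(any(ov))
  expect_true(all(abs(st2@stdMap[ov] - 2) < 1e-9))
})

test_that("artifact statistics count std-map exceedances", {
  sm <- array(0, c(20, 20, 10))
  expect_equal(artifactStatistics(sm, 1)$global_fraction, 0)
  smp <- sm
  idx <- seq_len(round(0.01 * length(sm)))
  smp[idx] <- 5
  as <- artifactStatistics(smp, 1)
  expect_equal(as$global_fraction, 0.01, tolerance = 1e-6)
  expect_gte(as$max_slice_fraction, as$global_fraction)
})

test_that("non-rigid stitching reduces overlap mismatch on a deformed pair", {
  dp <- deformedPair()
  stR <- suppressWarnings(stitchMosaic(dp$tiles, nonRigid = FALSE))
  stN <- suppressWarnings(stitchMosaic(dp$tiles, nonRigid = TRUE,
                                       gridSpacingVox = 12,
                                       blockRadiusVox = 8,
                                       searchRadiusVox = 8,
                                       scoreThreshold = 0.4))
  ovR <- stR@provenance >= 2L
  ovN <- stN@provenance >= 2L
  expect_lt(mean(stN@stdMap[ovN]), mean(stR@stdMap[ovR]))
  # the well-aligned (non-rigid) mosaic has fewer artifact voxels
  thr <- 3 * stats::median(stN@stdMap[ovN])
  aR <- artifactStatistics(stR@stdMap, thr, ovR)$global_fraction
  aN <- artifactStatistics(stN@stdMap, thr, ovN)$global_fraction
  expect_lt(aN, aR)
})
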