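test_that("bone masking with a global threshold", {
  ap <- airwayPhantom()
  ph <- ap$phantom
  v <- ap$noisy
  expect_equal(sum(maskBone(v, max(v) + 1)), 0)
  expect_message(full <- maskBone(v, min(v) - 1), "full mask")
  expect_true(all(full))
  # planted bone rods at 5x tissue are recovered with Dice > 0.95
  bone <- maskBone(v, (ph@muTissue + 5 * ph@muTissue) / 2)
  truth <- ph@vol > 3 * ph@muTissue
  dice <- 2 * sum(bone & truth) / (sum(bone) + sum(truth))
  expect_gt(dice, 0.95)
})

test_that("intermeans threshold splits a bimodal mixture at the midpoint", {
  set.seed(12)
  v <- c(rnorm(5000, 0.2, 0.02), rnorm(5000, 0.8, 0.02))
  thr <- mosaicCT:::intermeansThreshold(v)
  expect_equal(thr, 0.5, tolerance = 0.02)
})

test_that("slice-wise thresholds fall between the air and tissue modes", {
  ap <- airwayPhantom()
  first <- isoThresholdSlicewise(ap$noisy,
                                 cylinderMask = autoCylinderMask(ap$noisy))
  frac <- mean(first$thresholds > 0.1 * 2800 & first$thresholds < 0.9 * 2800)
  expect_gte(frac, 0.95)
  # degenerate (single-valued) slices borrow the nearest threshold
  v2 <- ap$noisy
  v2[, , 5] <- 1
  expect_warning(r2 <- isoThresholdSlicewise(v2), "degenerate")
  expect_equal(r2$thresholds[5],
               r2$thresholds[which(!seq_along(r2$thresholds) %in% 5)][
                 which.min(abs(setdiff(seq_along(r2$thresholds), 5) - 5))])
})

test_that("connectivity keeps the seeded component only", {
  m <- array(FALSE, c(30, 30, 30))
  m[10:20, 10:20, 20:30] <- TRUE          # block touching the top face
  set.seed(3)
  speck <- cbind(sample(1:30, 20), sample(1:30, 20), sample(1:8, 20, replace = TRUE))
  m[speck] <- TRUE
  out <- extractConnectedAirways(m)
  expect_true(all(out[10:20, 10:20, 20:30]))
  expect_equal(sum(out), 11 * 11 * 11)  # speckles removed
  # two components of equal size: the one touching the top face wins
  m2 <- array(FALSE, c(20, 20, 20))
  m2[2:6, 2:6, 14:20] <- TRUE    # touches top
  m2[12:16, 12:16, 2:8] <- TRUE  # same size, interior
  out2 <- extractConnectedAirways(m2)
  expect_true(all(out2[2:6, 2:6, 14:20]))
  expect_false(any(out2[12:16, 12:16, 2:8]))
  expect_error(extractConnectedAirways(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("connected airspace volume matches the phantom bookkeeping", {
  ph <- airwayPhantom()$phantom
  mask <- ph@airMask
  # plant disconnected pockets outside the lung boundary
  m2 <- mask
  m2[2:5, 2:5, 2:5] <- TRUE
  m2[210:214, 2:6, 50:54] <- TRUE
  out <- extractConnectedAirways(m2)
  lab <- mosaicCT:::conncomp3d_cpp(mask)
  sizes <- tabulate(lab[lab > 0])
  top <- unique(as.vector(lab[, , dim(mask)[3]])); top <- top[top > 0]
  truthN <- max(sizes[top])
  expect_lt(abs(sum(out) - truthN) / truthN, 0.02)
})

test_that("refinement is idempotent on binary volumes and nests in the dilation", {
  m <- array(FALSE, c(40, 40, 20))
  m[10:30, 10:30, 5:15] <- TRUE
  v <- array(2800, c(40, 40, 20))
  v[m] <- 0
  ref <- refineSegmentation(v, m, dilationRadius = 2, sharpnessAmount = 0,
                            voxelSizeUm = 2.75)
  expect_equal(ref$mask, m)
  # sharpness 0 equals the plain second pass
  ref1 <- refineSegmentation(v, m, dilationRadius = 2, sharpnessAmount = 1,
                             voxelSizeUm = 2.75)
  expect_equal(ref1$mask, m)   # binary volume: sharpening changes nothing
  # final mask always inside the dilated first-pass mask
  ap <- airwayPhantom()
  first <- isoThresholdSlicewise(ap$noisy,
                                 cylinderMask = autoCylinderMask(ap$noisy))
  air <- extractConnectedAirways(first$mask)
  ref2 <- refineSegmentation(ap$noisy, air, dilationRadius = 3,
                             voxelSizeUm = 2.75)
  dil <- mosaicCT:::dilate3d_cpp(air, 3)
  expect_true(all(dil[ref2$mask]))
})

test_that("raising per-slice thresholds never shrinks the air mask", {
  ap <- airwayPhantom()
  v <- ap$noisy
  first <- isoThresholdSlicewise(v)
  thr <- first$thresholds
  maskAt <- function(thr) {
    m <- array(FALSE, dim(v))
    for (z in seq_len(dim(v)[3])) m[, , z] <- v[, , z] < thr[z]
    m
  }
  m1 <- maskAt(thr)
  m2 <- maskAt(thr + 50)
  expect_true(all(m2[m1]))
  expect_gte(sum(m2), sum(m1))
})

test_that("segmentation recovers the phantom air volume within 5%", {
  ap <- airwayPhantom()
  seg <- segmentAirways(ap$noisy, voxelSizeUm = 2.75)
  gt <- airVolumeMm3(ap$phantom)
  est <- seg@volumeCm3 * 1000
  expect_lt(abs(est - gt) / gt, 0.05)
  expect_false(any(seg@airwayMask & seg@boneMask))
})
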