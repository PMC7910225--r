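test_that("foam phantom hits the target air fraction and is reproducible", {
  ph <- foamSmall()
  expect_gte(airFraction(ph), 0.57)
  expect_lte(airFraction(ph), 0.63)
  vox_mm3 <- (2.75e-3)^3
  expect_equal(airVolumeMm3(ph), sum(ph@airMask) * vox_mm3)
  ph2 <- makeFoamPhantom(c(160, 160, 160), 2.75, 0.6, seed = 11)
  expect_identical(ph@vol, ph2@vol)
  expect_identical(ph@airMask, ph2@airMask)
})

test_that("zero target air fraction yields a solid block", {
  ph <- makeFoamPhantom(c(48, 48, 48), 2.75, 0.0, seed = 1)
  expect_equal(sum(ph@airMask), 0)
  expect_true(all(ph@vol[ph@lungMask] > 0))
})

test_that("unreachable air fractions are refused", {
  expect_error(makeFoamPhantom(c(48, 48, 48), 2.75, 0.93, seed = 1),
               "unreachable")
})

test_that("the carved airspace is one connected component with the trachea", {
  ph <- foamSmall()
  lab <- mosaicCT:::conncomp3d_cpp(ph@airMask)
  sizes <- tabulate(lab[lab > 0])
  top <- unique(as.vector(lab[, , dim(ph@airMask)[3]]))
  top <- top[top > 0]
  expect_gt(sum(sizes[top]) / sum(sizes), 0.99)
})

test_that("deformation model is zero at t = 0 and grows linearly", {
  dm <- makeDeformationModel(c(64, 64, 64), ratePerS = 0.05, seed = 3)
  xs <- seq(5, 60, by = 7)
  u0 <- deformationAt(dm, 0, xs, xs, xs)
  expect_true(all(u0 == 0))
  m <- vapply(c(10, 20, 40, 80), function(t)
    max(sqrt(rowSums(deformationAt(dm, t, xs, xs, xs)^2))), numeric(1))
  expect_true(all(diff(m) > 0))
  expect_equal(m[4] / m[1], 8, tolerance = 1e-8)  # linear in t
})
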