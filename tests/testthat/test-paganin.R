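test_that("optics derivations: wavelength and attenuation at 21 keV", {
  opt <- OpticsConfig()
  expect_equal(opt@wavelengthM, 5.904e-11, tolerance = 1e-4)
  expect_equal(opt@delta / opt@beta, 714.3, tolerance = 1e-3)
  expect_equal(opt@muInvM, 59.6, tolerance = 1e-3)
  expect_error(OpticsConfig(delta = -1), "positive|> 0")
})

test_that("constant frames retrieve -log(c)/mu exactly", {
  opt <- OpticsConfig()
  for (c0 in c(0.3, 0.8, 1.0)) {
    r <- paganinRetrieve(matrix(c0, 20, 24), opt)
    expect_equal(r$muT, matrix(-log(c0), 20, 24), tolerance = 1e-12)
    expect_equal(r$thicknessM, r$muT / opt@muInvM)
  }
})

test_that("retrieval inverts the simulator's forward transfer exactly", {
  opt <- OpticsConfig()
  r2 <- outer((1:64 - 32)^2, (1:96 - 48)^2, "+")
  depth <- 0.3 * exp(-r2 / (2 * 12^2))
  illum <- makeIlluminationModel(c(64, 96), K = 0, seed = 2)
  fr <- applyContrastAndIllumination(depth, opt, illum, noise = FALSE,
                                     padPx = 0)
  trans <- (fr - illum@darkMean) / illum@meanFlat
  ret <- paganinRetrieve(trans, opt, padPx = 0)
  expect_lt(max(abs(ret$muT - depth)), 1e-6)
  # matched reflective padding on both sides stays close
  fr2 <- applyContrastAndIllumination(depth, opt, illum, noise = FALSE)
  trans2 <- (fr2 - illum@darkMean) / illum@meanFlat
  ret2 <- paganinRetrieve(trans2, opt)
  expect_lt(max(abs(ret2$muT - depth)), 1e-3)
})

test_that("the retrieval filter is a unit-DC low-pass", {
  opt <- OpticsConfig()
  fac <- phaseTransferFilter(c(32, 48), opt)
  expect_equal(fac[1, 1], 1)
  expect_true(all(fac >= 1))
  set.seed(8)
  frame <- 1 + 0.05 * mosaicCT:::gaussSmooth2d(matrix(rnorm(32 * 48), 32), 2)
  out <- paganinRetrieve(frame, opt, padPx = 0)
  Pin <- Mod(stats::fft(frame))^2
  Pout <- Mod(stats::fft(exp(-out$muT)))^2
  expect_true(all(Pout[-1] <= Pin[-1] * (1 + 1e-9)))
})

test_that("non-positive transmission pixels are floored with a warning", {
  opt <- OpticsConfig()
  fr <- matrix(0.5, 10, 10)
  fr[3, 3] <- -0.1
  expect_warning(paganinRetrieve(fr, opt), "floored 1")
})
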