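test_that("static correction normalizes linearly between dark and flat", {
  dark <- matrix(100, 8, 10)
  flat <- matrix(5000, 8, 10) + outer(1:8, 1:10)
  model <- new("FlatFieldModel", darkMean = dark, flatMean = flat,
               eigenflats = array(0, c(8, 10, 0)), eigenvalues = numeric(0))
  expect_equal(correctStatic(flat, model), matrix(1, 8, 10))
  expect_equal(correctStatic(dark, model), matrix(0, 8, 10))
  expect_equal(correctStatic(dark + 0.5 * (flat - dark), model),
               matrix(0.5, 8, 10))
  bad <- model
  bad@flatMean <- dark - 1
  expect_error(correctStatic(flat, bad), "80 pixels")
})

test_that("flat basis: identical flats give zero eigenvalues", {
  fr <- matrix(3000, 6, 8) + outer(1:6, 1:8)
  flats <- array(rep(fr, each = 10), c(10, 6, 8))
  m <- fitFlatBasis(flats, matrix(100, 6, 8), K = 3)
  expect_equal(m@eigenvalues, rep(0, 3))
  expect_equal(m@flatMean, fr + 100)
  expect_error(fitFlatBasis(flats, matrix(100, 6, 8), K = 10), "K")
})

test_that("flat basis recovers a planted rank-1 drift pattern", {
  set.seed(4)
  u <- matrix(rnorm(6 * 8), 6, 8)
  u <- u - mean(u); u <- u / sqrt(sum(u^2))
  base <- matrix(4000, 6, 8)
  cs <- rnorm(40, sd = 50)
  flats <- array(0, c(40, 6, 8))
  for (i in 1:40) flats[i, , ] <- base + cs[i] * u
  m <- fitFlatBasis(flats, matrix(0, 6, 8), K = 3)
  a <- abs(sum(m@eigenflats[, , 1] * u))
  expect_gt(a, 0.9999)
  expect_lt(m@eigenvalues[2] / m@eigenvalues[1], 1e-8)
})

test_that("flat basis recovers a planted 3-component drift subspace", {
  sc <- driftScan()
  illum <- sc$illum
  darkMean <- apply(sc$ps@darks, c(2, 3), mean)
  m <- fitFlatBasis(sc$ps@flats, darkMean, K = 3)
  U <- matrix(m@eigenflats, ncol = 3)
  V <- matrix(illum@components, ncol = 3)
  # principal angles between fitted and planted subspaces below 5 degrees
  sv <- svd(crossprod(U, V))$d
  angles <- acos(pmin(sv, 1)) * 180 / pi
  expect_true(all(angles < 5))
  # top-K reconstruction error of the flats is nonincreasing in K
  X <- matrix(sc$ps@flats, dim(sc$ps@flats)[1])
  Xc <- sweep(X, 2, colMeans(X))
  errK <- vapply(1:4, function(K) {
    mk <- fitFlatBasis(sc$ps@flats, darkMean, K = K)
    Uk <- matrix(mk@eigenflats, ncol = K)
    sum((Xc - Xc %*% Uk %*% t(Uk))^2)
  }, numeric(1))
  expect_true(all(diff(errK) <= 1e-6 * errK[1]))
})

test_that("dynamic correction recovers planted weights exactly", {
  set.seed(6)
  nr <- 12; nc <- 40
  flats <- array(0, c(30, nr, nc))
  base <- matrix(4000, nr, nc)
  us <- qr.Q(qr(matrix(rnorm(nr * nc * 2), nr * nc, 2)))
  for (i in 1:30)
    flats[i, , ] <- base + matrix(us %*% rnorm(2, sd = 60), nr, nc)
  dark <- matrix(100, nr, nc)
  m <- fitFlatBasis(flats, dark, K = 2)
  w_true <- c(0.7, -0.3) * 100
  raw <- dark + (m@flatMean - dark) +
    matrix(matrix(m@eigenflats, nr * nc, 2) %*% w_true, nr, nc)
  res <- correctDynamic(raw, m, marginCols = 10)
  expect_equal(res$weights, w_true, tolerance = 1e-6)
  expect_equal(res$frame, matrix(1, nr, nc), tolerance = 1e-6)
  # K = 0 model degenerates to the static correction
  m0 <- new("FlatFieldModel", darkMean = dark, flatMean = m@flatMean,
            eigenflats = array(0, c(nr, nc, 0)), eigenvalues = numeric(0))
  r0 <- correctDynamic(raw, m0)
  expect_equal(r0$frame, correctStatic(raw, m0))
})

test_that("dynamic correction beats static on a drifting-illumination scan", {
  dc <- driftCorrected()
  expect_lt(stripeMetric(dc$sD), stripeMetric(dc$sS))
  expect_lt(ringMetric(dc$rD), ringMetric(dc$rS))
})

test_that("ring metric behaves as a ring score", {
  n <- 101
  expect_equal(ringMetric(matrix(5, n, n)), 0)
  r <- sqrt(outer((1:n - 51)^2, (1:n - 51)^2, "+"))
  smooth <- exp(-r^2 / 500)
  base <- ringMetric(smooth)
  scores <- vapply(c(0.05, 0.1, 0.2), function(a)
    ringMetric(smooth + a * exp(-(r - 20)^2 / 2)), numeric(1))
  expect_true(all(diff(c(base, scores)) > 0))
  expect_lt(base, 0.01)
})
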