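test_that("plan geometry matches the wide-field lung protocol", {
  plan <- buildPlan(c(3, 3, 7), c(10.8, 10.8, 3.0), c(7.2, 2.75))
  expect_equal(nTiles(plan), 63)
  expect_equal(planExtentMm(plan)[3], 6 * 2.75 + 3.0)  # 19.5 mm
  single <- buildPlan(c(1, 1, 1), c(10.8, 10.8, 3.0), c(7.2, 2.75))
  expect_equal(nTiles(single), 1)
  expect_equal(planTiles(single)$order_index, 0L)
  expect_equal(unlist(planTiles(single)[1, c("x_mm", "y_mm", "z_mm")]),
               c(x_mm = 0, y_mm = 0, z_mm = 0))
  expect_error(buildPlan(c(2, 2, 2), c(1, 1, 1), c(2, 0.5)), "overlap")
})

test_that("zigzag order visits every tile once, moving to adjacent tiles", {
  grids <- list(c(3, 3, 7), c(5, 5, 9), c(1, 1, 4), c(4, 1, 1), c(2, 3, 2))
  for (g in grids) {
    plan <- buildPlan(g, c(10.8, 10.8, 3.0), c(7.2, 2.75))
    tiles <- planTiles(plan)
    expect_equal(nrow(unique(tiles[, c("i", "j", "k")])), prod(g))
    if (nrow(tiles) > 1) {
      d <- abs(diff(tiles$i)) + abs(diff(tiles$j)) + abs(diff(tiles$k))
      expect_true(all(d == 1L))
    }
  }
})

test_that("duration model reproduces the per-step averages and total bound", {
  timing <- TimingModel()
  plan <- buildPlan(c(3, 3, 7), c(10.8, 10.8, 3.0), c(7.2, 2.75), timing = timing)
  est <- estimateDuration(plan, timing)
  bd <- est$breakdown
  # 63 scans, 54 vertical and 8 horizontal moves
  expect_equal(bd$count[bd$event == "scan"], 63L)
  expect_equal(bd$count[bd$event == "vertical_move"], 54L)
  expect_equal(bd$count[bd$event == "horizontal_move"], 8L)
  # 2.75 mm at 550 um/s plus 3 s overhead is the printed 8.0 s average
  expect_equal(bd$each_s[bd$event == "vertical_move"], 8.0)
  expect_lt(est$total_s, 22 * 60)
  expect_equal(est$total_s, sum(bd$total_s))
  # single tile: scan plus calibration only
  single <- buildPlan(c(1, 1, 1), c(10.8, 10.8, 3.0), c(7.2, 2.75))
  est1 <- estimateDuration(single, timing)
  expect_equal(est1$total_s, timing@scanTimeS + timing@calibrationTimeS)
  # additivity: totals are the sum of the per-event breakdown of any plan
  plan2 <- buildPlan(c(2, 2, 3), c(10.8, 10.8, 3.0), c(7.2, 2.75))
  est2 <- estimateDuration(plan2, timing)
  expect_equal(est2$total_s, sum(est2$breakdown$total_s))
})

test_that("valid-region geometry: inscribed square of the recon circle", {
  expect_equal(validRegions(4000)$square_side_px, 2828)
  expect_equal(validRegions(2)$square_side_px, 1)
  vr <- validRegions(3927)
  expect_equal(vr$circle_diameter_px, 3927)
  expect_equal(vr$square_side_px, 2777)
  # a 100 px overlap is ~4% of the valid square width
  expect_equal(round(100 / vr$square_side_px * 100), 4)
})

test_that("overlap map lists adjacent pairs symmetrically", {
  plan <- buildPlan(c(2, 1, 3), c(10.8, 10.8, 3.0), c(7.2, 2.75),
                    pixelSizeUm = 2.75)
  om <- overlapMap(plan)
  vert <- om[om$axis == "z", ]
  expect_equal(unique(vert$overlap_mm), 3.0 - 2.75)
  expect_equal(unique(round(vert$overlap_px)), 91)  # (3.0-2.75)/0.00275
  # symmetric: every (a,b) row has its (b,a) mirror with swapped boxes
  for (r in seq_len(nrow(om))) {
    mir <- om[om$a == om$b[r] & om$b == om$a[r] & om$axis == om$axis[r], ]
    expect_equal(nrow(mir), 1L)
    expect_equal(c(mir$b_lo_mm, mir$b_hi_mm), c(om$a_lo_mm[r], om$a_hi_mm[r]))
  }
  # only grid-adjacent pairs appear
  tiles <- plan@tiles
  for (r in seq_len(nrow(om))) {
    a <- tiles[tiles$order_index == om$a[r], ]
    b <- tiles[tiles$order_index == om$b[r], ]
    expect_equal(abs(a$i - b$i) + abs(a$j - b$j) + abs(a$k - b$k), 1L)
  }
  # step equal to extent: zero overlap reported
  plan0 <- buildPlan(c(1, 1, 2), c(10.8, 10.8, 3.0), c(7.2, 3.0))
  expect_true(all(overlapMap(plan0)$overlap_mm == 0))
})

test_that("dataset bookkeeping: physical extent and storage size", {
  expect_equal(voxelExtentMm(9095, 2.75), 25.0, tolerance = 0.002)
  expect_equal(storageTb(c(9095, 9106, 7084), 2), 1.2, tolerance = 0.03)
  expect_equal(storageTb(c(6900, 6900, 6350), 2), 0.6, tolerance = 0.01)
})
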