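# Variable-flip-angle T1, MTR, ka and the B1-insensitive MT saturation.

test_that("VFA closed form round-trips SPGR signals and is scale-invariant", {
  s <- spgrPair(850, T1 = 1.0, tr = 0.015)
  fit <- vfaT1(s[1], s[2], c(4, 24), 0.015)
  expect_equal(fit$T1, 1.0, tolerance = 1e-12)
  expect_equal(fit$S0, 850, tolerance = 1e-9)
  expect_false(fit$flagged)
  expect_equal(vfaT1(2 * s[1], 2 * s[2], c(4, 24), 0.015)$T1, fit$T1)
})

test_that("non-physical VFA slopes are flagged, not fitted", {
  # signals growing faster than sin(alpha) imply a slope at or above 1
  fit1 <- vfaT1(100, 700, c(4, 24), 0.015)
  expect_true(fit1$flagged)
  expect_true(is.na(fit1$T1))
  bad <- vfaT1(10, 100, c(4, 24), 0.015)
  expect_true(bad$flagged)
  expect_true(is.na(bad$T1))
})

test_that("MTR, ka and delta evaluate their defining expressions", {
  expect_equal(computeMtr(1000, 700), 0.3)
  expect_equal(computeMtr(1000, 1000), 0)
  expect_equal(computeMtr(1000, 0), 1)
  expect_message(computeMtr(1000, 1100), "clipped")
  expect_equal(suppressMessages(computeMtr(1000, 1100)), -0.05)
  expect_error(computeMtr(0, 10), "positive")

  expect_equal(computeKa(0.3, 0.5), 0.6)
  expect_equal(computeKa(0, 1.2), 0)
  expect_error(computeKa(0.3, 0), "positive")

  # frozen value computed independently from the defining expression
  expect_equal(computeDelta(1.0, 0.015, 4 * pi / 180, 1000, 700),
               7.472972e-3, tolerance = 1e-6)
  expect_equal(computeDelta(1.0, 0.015, 4 * pi / 180, 900, 900), 0)
  expect_equal(computeDelta(0, 0.015, 0, 1000, 700), 0)
  expect_error(computeDelta(1, 0.015, 0.07, 1000, 0), "positive")
})

test_that("mtMaps recovers all five ground-truth maps from noiseless data", {
  gt <- tinyPhantom(seed = 13, grid = c(5, 5, 2), nRegions = 3)
  maps <- mtMaps(simulateMt(gt), array(TRUE, c(5, 5, 2)))
  for (p in c("T1", "T1s", "MTR", "ka", "delta"))
    expect_lt(max(abs(paramMap(maps, p) - paramMap(gt, p)) /
                  paramMap(gt, p)), 1e-8)
  mtr <- paramMap(maps, "MTR")
  expect_true(all(mtr >= 0 & mtr <= 1))
  # identity ka * T1s = MTR in every voxel
  expect_equal(paramMap(maps, "ka") * paramMap(maps, "T1s"), mtr)
})

test_that("delta is far less B1-sensitive than MTR", {
  gt <- tinyPhantom(seed = 14, grid = c(6, 6, 2), nRegions = 3)
  mask <- array(TRUE, c(6, 6, 2))
  biased <- mtMaps(simulateMt(gt, b1 = 0.9), mask)
  errDelta <- median(abs(paramMap(biased, "delta") / paramMap(gt, "delta") - 1))
  errMtr <- median(abs(paramMap(biased, "MTR") / paramMap(gt, "MTR") - 1))
  expect_lt(errDelta, errMtr)
  expect_lt(errDelta, 0.02)
  expect_gt(errMtr, 0.05)
})

test_that("delta and MTR rise monotonically with ground-truth saturation", {
  mtrs <- seq(0.05, 0.45, length.out = 9)
  vals <- t(vapply(mtrs, function(mtr) {
    gt <- makePhantom(phantomSpec(c(2, 2, 1), nRegions = 1,
                                  parameterRanges = list(MTR = c(mtr, mtr),
                                                         T1 = c(1.2, 1.2)),
                                  seed = 1))
    maps <- mtMaps(simulateMt(gt), array(TRUE, c(2, 2, 1)))
    c(paramMap(maps, "MTR")[1], paramMap(maps, "delta")[1])
  }, c(0, 0)))
  expect_true(all(diff(vals[, 1]) > 0))
  expect_true(all(diff(vals[, 2]) > 0))
})

test_that("mtMaps validates its acquisition metadata", {
  gt <- tinyPhantom(grid = c(3, 3, 1))
  mask <- array(TRUE, c(3, 3, 1))
  expect_error(mtMaps(simulateDwi(gt), mask), "MT acquisition")
  stack <- simulateMt(gt)
  broken <- signalStack(signalData(stack)[, , , c(1, 2, 3, 3), drop = FALSE],
                        acquisitionSpec("mt", tr = 0.015,
                                        flipAngles = c(4, 24, 4, 4),
                                        mtPulse = c(FALSE, FALSE, TRUE, TRUE)))
  expect_error(mtMaps(broken, mask), "missing or duplicated")
})
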