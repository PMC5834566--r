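# Least-squares and MCMC voxel fitting machinery.

test_that("NLLS recovers noiseless mono-exponential parameters exactly", {
  m <- modelSpec("monoexp_adc")
  b <- c(200, 400, 800)
  fit <- nllsFit(m, b, 1000 * exp(-b * 1e-3), init = c(800, 2e-3))
  expect_lt(relErr(estimate(fit)["S0"], 1000), 1e-6)
  expect_lt(relErr(estimate(fit)["ADC"], 1e-3), 1e-6)
  expect_lt(residualSS(fit), 1e-12)
  expect_true(isConverged(fit))
})

test_that("NLLS on constant signal pushes decay to its lower bound", {
  m <- modelSpec("monoexp_adc")
  b <- defaultBValues()
  fit <- nllsFit(m, b, rep(500, length(b)), init = c(500, 1e-3))
  expect_equal(unname(estimate(fit)["ADC"]), m@lower[2])
  expect_gt(residualSS(fit), 0)
})

test_that("NLLS recovers a noiseless IVIM signal at the nine b-values", {
  m <- modelSpec("ivim")
  b <- defaultBValues()
  y <- ivimSignal(b, 1000, 0.1, 1e-3, 10e-3)
  fit <- nllsFit(m, b, y, init = c(900, 0.2, 1.5e-3, 20e-3))
  truth <- c(S0 = 1000, f = 0.1, D = 1e-3, Dstar = 10e-3)
  expect_lt(max(relErr(estimate(fit), truth)), 1e-6)
})

test_that("fit input validation catches malformed problems", {
  m <- modelSpec("monoexp_adc")
  expect_error(nllsFit(m, c(1, 2), c(1, 2, 3), c(100, 1e-3)), "equal length")
  expect_error(nllsFit(m, 800, 500, c(100, 1e-3)), "fewer observations")
  expect_error(nllsFit(m, c(1, 2), c(NA, 2), c(100, 1e-3)), "non-finite")
  expect_error(nllsFit(m, c(1, 2), c(1, 2), c(-5, 1e-3)), "outside")
  expect_error(mcmcFit(m, c(1, 2), c(1, 2), c(100, 1e-3), chainLength = 10),
               "at least 1000")
  expect_error(mcmcFit(m, c(1, 2, 3), c(0, 0, 0), c(100, 1e-3)), "all-zero")
})

test_that("MCMC is seed-deterministic and matches the NLLS oracle", {
  b <- defaultBValues()
  for (case in list(
    list(m = modelSpec("monoexp_adc"), y = 1000 * exp(-b * 1e-3),
         init = c(800, 2e-3), design = b),
    list(m = modelSpec("t2star"), y = 900 * exp(-defaultEchoTimes() / 18),
         init = c(700, 10), design = defaultEchoTimes()),
    list(m = modelSpec("spgr", tr = 0.015), y = spgrPair(850, 1.2),
         init = c(500, 0.8), design = c(4, 24) * pi / 180))) {
    fm <- mcmcFit(case$m, case$design, case$y, case$init, seed = 3)
    fm2 <- mcmcFit(case$m, case$design, case$y, case$init, seed = 3)
    expect_identical(estimate(fm), estimate(fm2))
    fn <- nllsFit(case$m, case$design, case$y, case$init)
    expect_lt(median(relErr(estimate(fm), estimate(fn))), 0.01)
  }
})

test_that("MCMC posterior spread on pure noise dwarfs the noiseless spread", {
  m <- modelSpec("monoexp_adc")
  b <- defaultBValues()
  clean <- mcmcFit(m, b, 1000 * exp(-b * 1e-3), c(800, 2e-3), seed = 1)
  noise <- withr::with_seed(4, abs(rnorm(length(b), 0, 50)) + 1)
  noisy <- mcmcFit(m, b, noise, c(800, 2e-3), seed = 1)
  expect_gt(posteriorSpread(noisy)["ADC"],
            10 * posteriorSpread(clean)["ADC"])
})

test_that("volume fitting matches single-voxel fits and ignores voxel order", {
  gt <- makePhantom(phantomSpec(c(4, 4, 1), nRegions = 2, seed = 2))
  stack <- simulateDwi(gt)
  mask1 <- array(FALSE, c(4, 4, 1)); mask1[2, 3, 1] <- TRUE
  m <- modelSpec("ivim")
  maps1 <- fitVolume(m, stack, mask1)
  single <- nllsFit(m, bValues(stack), signalData(stack)[2, 3, 1, ],
                    init = fibromap:::defaultInit(m, signalData(stack)[2, 3, 1, ]))
  expect_equal(paramMap(maps1, "D")[2, 3, 1], unname(estimate(single)["D"]))

  # independence of processing order: a sub-mask reproduces the full-mask
  # values voxel for voxel (per-voxel seeds are position-derived)
  full <- array(TRUE, c(4, 4, 1))
  mapsFull <- fitVolume(m, stack, full, engine = "mcmc",
                        chainLength = 1000L, burnIn = 500L, seed = 5)
  mapsSub <- fitVolume(m, stack, mask1, engine = "mcmc",
                       chainLength = 1000L, burnIn = 500L, seed = 5)
  expect_equal(paramMap(mapsSub, "D")[2, 3, 1],
               paramMap(mapsFull, "D")[2, 3, 1])
  expect_true(is.na(paramMap(mapsSub, "D")[1, 1, 1]))

  # piecewise-constant phantom gives piecewise-constant maps
  expect_equal(length(unique(round(as.vector(paramMap(
    fitVolume(m, stack, full), "D")), 10))), 2L)

  expect_error(fitVolume(m, stack, array(FALSE, c(4, 4, 1))), "empty")
  expect_error(fitVolume(m, stack, array(TRUE, c(3, 3, 1))), "dimensions")
})

test_that("estimates respect bounds and rss falls as noise falls", {
  m <- modelSpec("ivim")
  b <- defaultBValues()
  y <- ivimSignal(b)
  rssAt <- function(sigma, seed) {
    yn <- withr::with_seed(seed, y + rnorm(length(b), 0, sigma))
    fit <- nllsFit(m, b, abs(yn), init = c(900, 0.2, 1.5e-3, 20e-3))
    expect_true(all(estimate(fit) >= m@lower - 1e-12))
    expect_true(all(estimate(fit) <= m@upper + 1e-12))
    residualSS(fit)
  }
  hi <- vapply(1:10, function(s) rssAt(20, s), 0)
  lo <- vapply(1:10, function(s) rssAt(2, s), 0)
  expect_gt(mean(hi), mean(lo))
})
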