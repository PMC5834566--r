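# Phantom generator, forward simulators, noise model, slide renderer and
# cohort generator.

test_that("phantom generation is seed-deterministic and respects ranges", {
  gt1 <- tinyPhantom(seed = 7)
  gt2 <- tinyPhantom(seed = 7)
  expect_identical(gt1@maps@maps, gt2@maps@maps)
  expect_identical(gt1@regions, gt2@regions)
  expect_false(identical(gt1@maps@maps, tinyPhantom(seed = 8)@maps@maps))

  rng <- defaultParameterRanges()
  for (p in names(rng)) {
    m <- paramMap(gt1, p)
    expect_gte(min(m), rng[[p]][1])
    expect_lte(max(m), rng[[p]][2] * 1.05 + 1e-12)  # Dstar floor at 1.05 D
  }
})

test_that("degenerate phantoms: one region is constant, pinned ranges force constants", {
  gt <- tinyPhantom(nRegions = 1L)
  for (p in mapNames(gt))
    expect_equal(length(unique(as.vector(paramMap(gt, p)))), 1L)

  gtPin <- makePhantom(phantomSpec(c(6, 6, 2), nRegions = 3,
                                   parameterRanges = list(D = c(1e-3, 1e-3)),
                                   seed = 3))
  expect_true(all(paramMap(gtPin, "D") == 1e-3))
})

test_that("phantom spec validation rejects bad inputs", {
  expect_error(phantomSpec(c(0, 4, 4)), "positive")
  expect_error(phantomSpec(parameterRanges = list(D = c(2e-3, 1e-3))),
               "inverted|malformed")
  expect_error(phantomSpec(noiseSigma = -1), "non-negative")
})

test_that("derived ground-truth maps satisfy the internal identities", {
  gt <- tinyPhantom(seed = 11, nRegions = 3)
  expect_equal(paramMap(gt, "ka"), paramMap(gt, "MTR") / paramMap(gt, "T1s"))
  expect_equal(paramMap(gt, "delta"),
               (gt@mtTr / paramMap(gt, "T1") + gt@mtAlphaNom^2 / 2) *
                 paramMap(gt, "MTR") / (1 - paramMap(gt, "MTR")))
  expect_true(all(paramMap(gt, "Dstar") > paramMap(gt, "D")))
  expect_true(all(paramMap(gt, "T1s") < paramMap(gt, "T1")))
})

test_that("DWI simulator evaluates the bi-exponential model exactly", {
  gt <- makePhantom(phantomSpec(c(2, 2, 1), nRegions = 1,
                                parameterRanges = list(
                                  S0 = c(1000, 1000), f = c(0.1, 0.1),
                                  D = c(1e-3, 1e-3), Dstar = c(10e-3, 10e-3)),
                                seed = 1))
  s <- simulateDwi(gt, c(0, 800))
  expect_equal(signalData(s)[1, 1, 1, 1], 1000)  # b = 0 identity
  expect_equal(signalData(s)[1, 1, 1, 2],
               1000 * (0.1 * exp(-8) + 0.9 * exp(-0.8)))

  # f = 0 nests the mono-exponential model
  gt0 <- makePhantom(phantomSpec(c(2, 2, 1), nRegions = 1,
                                 parameterRanges = list(f = c(0, 0)),
                                 seed = 2))
  b <- defaultBValues()
  s0 <- simulateDwi(gt0, b)
  mono <- outer(as.vector(paramMap(gt0, "S0")),
                exp(-b * paramMap(gt0, "D")[1]))
  expect_equal(as.vector(signalData(s0)), as.vector(mono))

  expect_error(simulateDwi(gt, c(0, 100, 100)), "increasing")
  expect_error(simulateDwi(gt, c(-5, 100)), "non-negative")
})

test_that("UTE simulator is a two-pool sum with the stated limits", {
  gt <- makePhantom(phantomSpec(c(2, 2, 1), nRegions = 1,
                                parameterRanges = list(
                                  S0 = c(1000, 1000), ratio = c(0.2, 0.2),
                                  T2short = c(0.5, 0.5), T2long = c(20, 20)),
                                seed = 1))
  te <- defaultEchoTimes()
  s <- signalData(simulateUte(gt, te))[1, 1, 1, ]
  expect_equal(s, utePoolSignal(te, 1000, 800, 0.5, 20))
  # short pool is numerically dead by the last conventional echo
  shortPart <- 200 * exp(-20.6 / 0.5)
  expect_lt(shortPart / 200, 1e-10)
  # degenerate equal relaxation times collapse to one exponential
  gtEq <- makePhantom(phantomSpec(c(2, 2, 1), nRegions = 1,
                                  parameterRanges = list(
                                    T2short = c(20, 20), T2long = c(20, 20)),
                                  seed = 1))
  sEq <- signalData(simulateUte(gtEq, te))[1, 1, 1, ]
  A <- paramMap(gtEq, "S0")[1]
  expect_equal(sEq, A * exp(-te / 20))
})

test_that("MT simulator: MTR = 0 collapses to the reference volumes", {
  gt <- makePhantom(phantomSpec(c(3, 3, 1), nRegions = 2,
                                parameterRanges = list(MTR = c(1e-9, 1e-9)),
                                seed = 4))
  s <- signalData(simulateMt(gt))
  expect_equal(s[, , , 1], s[, , , 3], tolerance = 1e-6)
  expect_equal(s[, , , 2], s[, , , 4], tolerance = 1e-6)
})

test_that("Rician noise: identity at sigma 0, Rayleigh mean at S = 0, seeded", {
  gt <- tinyPhantom()
  s <- simulateDwi(gt)
  expect_identical(addNoise(s, 0), s)
  n1 <- addNoise(s, 5, seed = 9)
  expect_identical(signalData(n1), signalData(addNoise(s, 5, seed = 9)))
  expect_false(identical(signalData(n1), signalData(addNoise(s, 5, seed = 10))))
  expect_error(addNoise(s, -1), "non-negative")

  # zero-signal magnitude noise has the Rayleigh mean sigma * sqrt(pi / 2)
  zero <- signalStack(array(0, c(50, 50, 40, 1)),
                      acquisitionSpec("dwi", bvalues = 0))
  draws <- signalData(addNoise(zero, 3, seed = 2))
  expect_equal(mean(draws), 3 * sqrt(pi / 2), tolerance = 0.01)

  # noise floor: mean noisy magnitude is not below the noiseless signal
  noisy <- addNoise(s, 30, seed = 1)
  expect_gt(mean(signalData(noisy)) - mean(signalData(s)), 0)
})

test_that("cohort generator hits the requested effect size and sign pattern", {
  co <- makeCohort(cohortSpec(nSections = 18, seed = 5))
  expect_identical(co, makeCohort(cohortSpec(nSections = 18, seed = 5)))

  # noiseless lines are exactly correlated
  co0 <- makeCohort(cohortSpec(nSections = 12, collagenMtR = 0.85,
                               noiseSd = 0, seed = 2))
  expect_equal(abs(cor(co0$ka, co0$picrosirius)), 1)
  expect_equal(cor(co0$T1, co0$picrosirius), -1)

  # sign pattern of the collagen couplings
  big <- makeCohort(cohortSpec(nSections = 400, seed = 3))
  for (p in c("ka", "delta", "MTR", "f", "fDstar"))
    expect_gt(cor(big[[p]], big$picrosirius), 0)
  for (p in c("T1", "T1s", "ADC", "D", "T2long"))
    expect_lt(cor(big[[p]], big$picrosirius), 0)

  # Monte-Carlo calibration: mean sample r near the target
  rs <- vapply(1:200, function(i) {
    co <- makeCohort(cohortSpec(1000, 0.85, seed = i))
    cor(co$ka, co$picrosirius)
  }, 0)
  expect_lt(abs(mean(rs) - 0.85), 0.02)
})

test_that("slide renderer lays down exact stain fractions and vessel counts", {
  s <- renderHistologySlide(0.25, 0.1, nVessels = 30, size = c(128, 128),
                            seed = 6)
  nT <- sum(s$tissueMask)
  expect_equal(sum(s$collagenMask) / nT, 0.25, tolerance = 0.005)
  expect_equal(sum(s$hypoxiaMask) / nT, 0.10, tolerance = 0.005)
  expect_false(any(s$collagenMask & s$hypoxiaMask))
  expect_equal(max(EBImage::bwlabel(s$vesselMask * 1)), 30)

  s0 <- renderHistologySlide(0, size = c(64, 64), seed = 1)
  expect_equal(sum(s0$collagenMask), 0)
  expect_error(renderHistologySlide(0.7, 0.4), "capacity")
  expect_identical(renderHistologySlide(0.2, seed = 3, size = c(64, 64)),
                   renderHistologySlide(0.2, seed = 3, size = c(64, 64)))
})
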