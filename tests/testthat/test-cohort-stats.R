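# ROI medians, Dice, log-CoV, correlation matrix, PLSR with LOOCV.

test_that("roiMedian is the outlier-damped in-mask median", {
  m <- array(c(1, 2, 3, 100), c(4, 1, 1))
  roi <- array(TRUE, c(4, 1, 1))
  expect_equal(roiMedian(m, roi), 2.5)
  expect_equal(roiMedian(array(c(1, 2, 3, 100), c(4, 1, 1)),
                         array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1))), 2)
  mNA <- m; mNA[4] <- NA
  expect_message(expect_equal(roiMedian(mNA, roi), 2), "excluded")
  expect_error(roiMedian(m, array(FALSE, c(4, 1, 1))), "empty")
  expect_error(roiMedian(array(NA_real_, c(2, 1, 1)),
                         array(TRUE, c(2, 1, 1))), "flagged")
})

test_that("Dice coefficient handles identity, disjointness and emptiness", {
  a <- array(FALSE, c(10, 10, 1)); a[1:5, , 1] <- TRUE
  b <- array(FALSE, c(10, 10, 1)); b[3:7, , 1] <- TRUE
  expect_equal(diceCoefficient(a, a), 1)
  expect_equal(diceCoefficient(a, !a), 0)
  expect_equal(diceCoefficient(a, b), 2 * 30 / (50 + 50))
  expect_equal(diceCoefficient(a & FALSE, b & FALSE), 1)
  expect_error(diceCoefficient(a, array(TRUE, c(5, 5, 1))), "dimensions")
})

test_that("log-CoV matches its defining formula and is scale-invariant", {
  expect_equal(covLog(c(5, 7, 9), c(5, 7, 9)), 0)
  # all pairs at ratio e^0.1: sigma_w^2 = 0.005
  x <- c(1, 2, 4, 8)
  expect_equal(covLog(x, x * exp(0.1)), 100 * sqrt(exp(0.005) - 1),
               tolerance = 1e-12)
  expect_equal(covLog(x, x * exp(0.1)), 7.08, tolerance = 1e-2)
  expect_equal(covLog(x, x * 1.13), covLog(10 * x, 11.3 * x))
  expect_equal(covLog(x, x * exp(0.1), simple = TRUE), 100 * sqrt(0.005))
  expect_error(covLog(c(1, -1), c(1, 1)), "positive")
  expect_error(covLog(1, 2), "at least two")
})

test_that("correlation matrix applies the Bonferroni family threshold", {
  co <- makeCohort(cohortSpec(nSections = 18, seed = 21))
  cm <- correlationMatrix(co, familyAlpha = 0.05, nComparisons = 4)
  expect_equal(attr(cm, "adjustedAlpha"), 0.0125)
  expect_identical(cm$significant, cm$p < 0.0125)

  # exact linear dependence
  co$lin <- 2 * co$picrosirius
  cmLin <- correlationMatrix(co, mrParams = "lin",
                             histoParams = "picrosirius")
  expect_equal(cmLin$r, 1)

  # significance flags are monotone in the family alpha
  cmLoose <- correlationMatrix(co, familyAlpha = 0.20, nComparisons = 4)
  expect_true(all(cm$significant <= cmLoose$significant))

  co$flat <- rep(1, nrow(co))
  expect_error(correlationMatrix(co, mrParams = "flat"), "zero-variance")
  expect_error(correlationMatrix(co[1:3, ]), "at least 4")
})

test_that("large synthetic cohorts reproduce the generator's effect size", {
  co <- makeCohort(cohortSpec(nSections = 1000, collagenMtR = 0.85,
                              seed = 31))
  cm <- correlationMatrix(co)
  rka <- cm[cm$mrParam == "ka" & cm$histoParam == "picrosirius", "r"]
  expect_lt(abs(rka - 0.85), 0.05)
})

test_that("t-transform p-values agree with a permutation null", {
  co <- makeCohort(cohortSpec(nSections = 16, collagenMtR = 0.6, seed = 41))
  for (p in c("MTR", "T2short", "ADC")) {
    pt <- cor.test(co[[p]], co$picrosirius)$p.value
    pp <- permutationCorTest(co[[p]], co$picrosirius, nPerm = 10000,
                             seed = 5)
    tol <- max(0.02, 4 * sqrt(pt * (1 - pt) / 10000))
    expect_lt(abs(pt - pp), tol)
  }
})

test_that("PLSR LOOCV equals a brute-force refit loop", {
  co <- makeCohort(cohortSpec(nSections = 16, seed = 51))
  # single predictor: PLSR with 1 LV is simple linear regression, so the
  # oracle is an explicit lm() leave-one-out loop
  res <- plsrLoocv(co, "ka", "picrosirius", nLv = 1)
  oracle <- vapply(seq_len(16), function(i) {
    fit <- lm(picrosirius ~ ka, data = co[-i, ])
    unname(predict(fit, co[i, ]))
  }, 0)
  expect_equal(res$predictions, oracle, tolerance = 1e-10)
  expect_equal(res$nrmse,
               sqrt(mean((oracle - co$picrosirius)^2)) /
                 diff(range(co$picrosirius)))

  # perfect linear response recovered to numerical zero
  co$resp <- 3 + 2 * co$ka
  expect_lt(plsrLoocv(co, "ka", "resp", nLv = 1)$nrmse, 1e-6)

  # record order cannot matter
  perm <- sample(seq_len(16))
  resPerm <- plsrLoocv(co[perm, ], "ka", "picrosirius", nLv = 1)
  expect_equal(resPerm$nrmse, res$nrmse)
})

test_that("NIPALS PLSR agrees with an independent implementation", {
  skip_if_not_installed("mixOmics")
  co <- makeCohort(cohortSpec(nSections = 18, seed = 61))
  preds <- c("MTR", "T1", "T1s", "ka", "delta")
  X <- as.matrix(co[, preds])
  y <- co$picrosirius
  for (k in 1:2) {
    mine <- plsrLoocv(co, preds, "picrosirius", nLv = k)
    ext <- mixOmics::pls(X, y, ncomp = k, mode = "regression",
                         scale = TRUE)
    extPred <- predict(ext, X)$predict[, 1, k]
    Xs <- scale(X)
    minePred <- drop(Xs %*% mine$coefficients) + mean(y)
    expect_equal(unname(minePred), unname(extPred), tolerance = 1e-8)
  }
})

test_that("LV selection minimises the cross-validated error", {
  co <- makeCohort(cohortSpec(nSections = 18, seed = 71))
  preds <- c("MTR", "T1", "T1s", "ka", "delta")
  res <- plsrLoocv(co, preds, "picrosirius")
  expect_equal(res$nLv, which.min(res$nrmseByLv))
  expect_equal(res$nrmse, min(res$nrmseByLv))
  expect_error(plsrLoocv(transform(co, k0 = 1), "ka", "k0"), "constant")
})
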