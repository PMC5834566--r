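## Cohort statistics layer: ROI medians, Dice overlap, log-transformed
## repeat-measures CoV, Bonferroni-corrected Pearson correlation, and
## NIPALS partial least-squares regression with leave-one-out
## cross-validation.

#' Median of a parameter map inside an ROI
#'
#' Summarises a voxel map by the median of the in-mask voxels, the
#' outlier-resistant summary appropriate when partial-volume voxels
#' contaminate an ROI. Flagged/sentinel (`NA`/non-finite) voxels are
#' excluded, with a message reporting how many.
#'
#' @param map 3D numeric array (one entry of a [ParameterMaps-class]).
#' @param roi logical array of the same dimensions.
#' @return The median, a single number.
#' @examples
#' m <- array(c(1, 2, 3, 100), c(4, 1, 1))
#' roiMedian(m, array(TRUE, c(4, 1, 1)))  # 2.5
#' @export
roiMedian <- function(map, roi) {
  if (!identical(dim(map), dim(roi)))
    stop("map and roi dimensions differ", call. = FALSE)
  if (!any(roi)) stop("roi is empty", call. = FALSE)
  v <- map[roi]
  bad <- !is.finite(v)
  if (all(bad))
    stop("all ROI voxels are flagged/sentinel", call. = FALSE)
  if (any(bad))
    message("roiMedian: excluded ", sum(bad), " flagged voxel(s)")
  stats::median(v[!bad])
}

#' Sorenson-Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two binary masks of equal
#' dimensions; defined as 1 when both masks are empty.
#'
#' @param maskA,maskB logical (or 0/1) arrays of identical dimensions.
#' @return Dice coefficient in \[0, 1\].
#' @examples
#' diceCoefficient(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
diceCoefficient <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB)) ||
      length(maskA) != length(maskB))
    stop("mask dimensions differ", call. = FALSE)
  a <- maskA != 0
  b <- maskB != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Repeat-measures coefficient of variation on log-transformed values
#'
#' For positive-constrained parameters measured twice per subject the
#' within-subject variability is computed on the log scale:
#' `d_i = ln x_i1 - ln x_i2`, `sigma_w^2 = mean(d_i^2) / 2`, and
#' `CoV% = 100 sqrt(exp(sigma_w^2) - 1)`. Scale-invariant by construction.
#' The simpler first-order approximation `100 sigma_w` is available via
#' `simple = TRUE`.
#'
#' @param x1,x2 paired positive measurements (first and second observer or
#'   repeat), or `x1` an n x 2 matrix with `x2` missing.
#' @param simple use the first-order approximation.
#' @return CoV as a percentage.
#' @examples
#' covLog(c(1, 2, 4), c(1, 2, 4) * exp(0.1))  # ~7.08
#' @export
covLog <- function(x1, x2 = NULL, simple = FALSE) {
  if (is.null(x2)) {
    if (is.null(dim(x1)) || ncol(x1) != 2L)
      stop("supply paired vectors or an n x 2 matrix", call. = FALSE)
    x2 <- x1[, 2]
    x1 <- x1[, 1]
  }
  if (length(x1) != length(x2) || length(x1) < 2L)
    stop("need at least two pairs", call. = FALSE)
  if (any(x1 <= 0) || any(x2 <= 0))
    stop("log-CoV requires strictly positive values", call. = FALSE)
  d <- log(x1) - log(x2)
  sw2 <- mean(d^2) / 2
  if (simple) 100 * sqrt(sw2) else 100 * sqrt(exp(sw2) - 1)
}

#' Pearson correlation matrix of MR versus histological parameters
#'
#' Pearson `r` and the exact two-sided t-transform p-value
#' (`n - 2` degrees of freedom) for every MR x histology pair, with a
#' Bonferroni-adjusted significance threshold
#' `familyAlpha / nComparisons` (by default the number of histological
#' markers each MR parameter is compared against).
#'
#' @param cohort data frame with one row per matched section.
#' @param mrParams,histoParams column names to correlate; defaults cover
#'   the standard parameter set where present.
#' @param familyAlpha family-wise error rate.
#' @param nComparisons Bonferroni divisor; defaults to
#'   `length(histoParams)`.
#' @return A data frame with columns `mrParam`, `histoParam`, `r`, `p`,
#'   `n`, `significant`, carrying the adjusted threshold as attribute
#'   `adjustedAlpha`.
#' @examples
#' cm <- correlationMatrix(makeCohort(cohortSpec(seed = 4)))
#' attr(cm, "adjustedAlpha")
#' subset(cm, histoParam == "picrosirius" & mrParam == "ka")
#' @export
correlationMatrix <- function(cohort,
                              mrParams = intersect(cohortParamTable()$param,
                                                   names(cohort)),
                              histoParams = intersect(
                                c("necrosis", "mvd", "pimonidazole",
                                  "picrosirius"), names(cohort)),
                              familyAlpha = 0.05,
                              nComparisons = length(histoParams)) {
  if (nrow(cohort) < 4L)
    stop("need at least 4 records", call. = FALSE)
  for (p in c(mrParams, histoParams))
    if (stats::sd(cohort[[p]]) == 0)
      stop("zero-variance column: ", p, call. = FALSE)
  adjusted <- familyAlpha / nComparisons
  grid <- expand.grid(mrParam = mrParams, histoParam = histoParams,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- cohort[[grid$mrParam[i]]]
    y <- cohort[[grid$histoParam[i]]]
    ok <- is.finite(x) & is.finite(y)
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
  out <- cbind(grid, do.call(rbind, res))
  out$significant <- out$p < adjusted
  attr(out, "adjustedAlpha") <- adjusted
  out
}

#' Permutation null for a Pearson correlation
#'
#' Two-sided permutation p-value for `cor(x, y)` from `nPerm` seeded
#' permutations of `y` (add-one estimator). An independent check of the
#' t-transform p-values on small cohorts.
#'
#' @param x,y numeric vectors.
#' @param nPerm number of permutations.
#' @param seed integer RNG seed.
#' @return Permutation p-value.
#' @export
permutationCorTest <- function(x, y, nPerm = 10000L, seed = 1L) {
  r0 <- abs(stats::cor(x, y))
  withSeed(seed, {
    rp <- vapply(seq_len(nPerm),
                 function(i) abs(stats::cor(x, sample(y))), 0)
    (1 + sum(rp >= r0)) / (nPerm + 1)
  })
}

## NIPALS PLSR core for a single response: X already z-scored, y centred.
## Returns weights W, loadings P, response loadings q, and the regression
## coefficients on the standardised scale for 1..nLv components.
nipalsPls <- function(X, y, nLv) {
  p <- ncol(X)
  W <- matrix(0, p, nLv)
  P <- matrix(0, p, nLv)
  q <- numeric(nLv)
  Xd <- X
  yd <- y
  for (k in seq_len(nLv)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) { nLv <- k - 1L; break }
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    P[, k] <- drop(crossprod(Xd, t)) / tt
    q[k] <- sum(yd * t) / tt
    W[, k] <- w
    Xd <- Xd - tcrossprod(t, P[, k])
    yd <- yd - q[k] * t
  }
  if (nLv == 0L) stop("response is orthogonal to all predictors",
                      call. = FALSE)
  W <- W[, seq_len(nLv), drop = FALSE]
  P <- P[, seq_len(nLv), drop = FALSE]
  q <- q[seq_len(nLv)]
  B <- W %*% solve(crossprod(P, W), q)
  list(W = W, P = P, q = q, coefficients = drop(B), nLv = nLv)
}

#' Partial least-squares regression with leave-one-out cross-validation
#'
#' NIPALS PLSR of a single response on z-scored predictors (scaling
#' refitted inside every cross-validation fold). Leave-one-out
#' cross-validation produces out-of-sample predictions, summarised as
#' `NRMSE = RMSE(pred, obs) / range(obs)` (or `/ mean(obs)` with
#' `normalise = "mean"`). With `nLv = NULL` the number of latent variables
#' is chosen as the minimiser of the LOOCV NRMSE. With a single predictor
#' the procedure reduces to cross-validated simple linear regression, the
#' per-parameter comparison mode.
#'
#' @param cohort data frame with one row per section.
#' @param predictors predictor column names.
#' @param response response column name.
#' @param nLv number of latent variables, or `NULL` to select by LOOCV.
#' @param normalise NRMSE normaliser: `"range"` (default) or `"mean"`.
#' @return A list: `nrmse`, `nLv`, `predictions`, `observed`, `loadings`
#'   (full-fit X loadings), `weights`, `coefficients` (standardised scale),
#'   and `nrmseByLv` when the LV count was selected.
#' @examples
#' co <- makeCohort(cohortSpec(seed = 5))
#' plsrLoocv(co, c("MTR", "T1", "T1s", "ka", "delta"), "picrosirius")$nrmse
#' @export
plsrLoocv <- function(cohort, predictors, response, nLv = NULL,
                      normalise = c("range", "mean")) {
  normalise <- match.arg(normalise)
  X <- as.matrix(cohort[, predictors, drop = FALSE])
  y <- cohort[[response]]
  n <- nrow(X)
  if (stats::sd(y) == 0) stop("constant response", call. = FALSE)
  if (n <= length(predictors))
    warning("fewer records than predictors + 1; ",
            "cross-validated error is the only reliable summary")
  if (n < 3L) stop("need at least 3 records", call. = FALSE)

  fitPredict <- function(train, test, k) {
    mu <- colMeans(X[train, , drop = FALSE])
    sg <- apply(X[train, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    Xs <- sweep(sweep(X[train, , drop = FALSE], 2, mu), 2, sg, "/")
    ym <- mean(y[train])
    fit <- nipalsPls(Xs, y[train] - ym, k)
    Xt <- sweep(sweep(X[test, , drop = FALSE], 2, mu), 2, sg, "/")
    drop(Xt %*% fit$coefficients) + ym
  }
  loocv <- function(k) {
    vapply(seq_len(n),
           function(i) fitPredict(setdiff(seq_len(n), i), i, k), 0)
  }
  nrmseOf <- function(pred) {
    scale <- if (normalise == "range") diff(range(y)) else mean(y)
    sqrt(mean((pred - y)^2)) / scale
  }

  nrmseByLv <- NULL
  if (is.null(nLv)) {
    kMax <- max(1L, min(length(predictors), n - 2L))
    nrmseByLv <- vapply(seq_len(kMax), function(k) nrmseOf(loocv(k)), 0)
    nLv <- which.min(nrmseByLv)
  }
  pred <- loocv(nLv)

  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[sg == 0] <- 1
  full <- nipalsPls(sweep(sweep(X, 2, mu), 2, sg, "/"), y - mean(y), nLv)
  list(nrmse = nrmseOf(pred), nLv = full$nLv, predictions = pred,
       observed = y, loadings = full$P, weights = full$W,
       coefficients = full$coefficients, nrmseByLv = nrmseByLv)
}
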