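## Synthetic cohort generator: matched MR / histology sections with a
## tunable collagen-MT effect size and uncorrelated filler markers.

#' Construct a CohortSpec
#'
#' @param nSections number of matched MR/histology sections (>= 4).
#' @param collagenMtR target Pearson correlation magnitude between collagen
#'   stain fraction and the collagen-coupled MR parameters, in (-1, 1).
#' @param noiseSd residual scatter multiplier: 1 calibrates the expected
#'   sample correlation magnitude to `collagenMtR`; 0 gives exact lines.
#' @param seed integer RNG seed.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(nSections = 18L, collagenMtR = 0.85, noiseSd = 1,
                       seed = 1L) {
  new("CohortSpec", nSections = as.integer(nSections),
      collagenMtR = as.numeric(collagenMtR), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

## Per-parameter cohort marginals: mean, SD, and the sign of the coupling
## to collagen (0 = uncorrelated filler). Values are typical ROI medians
## for soft-tissue tumour at 1.5 T.
cohortParamTable <- function() {
  data.frame(
    param = c("ka", "delta", "MTR", "f", "fDstar",
              "T1", "T1s", "ADC", "D", "T2long",
              "T2short", "Dstar", "ratio"),
    mean = c(0.40, 0.010, 0.30, 0.15, 2.0e-3,
             1.20, 0.65, 1.05e-3, 1.0e-3, 22,
             0.50, 20e-3, 0.20),
    sd = c(0.10, 0.003, 0.06, 0.05, 0.8e-3,
           0.15, 0.10, 0.15e-3, 0.15e-3, 3,
           0.08, 8e-3, 0.04),
    sign = c(1, 1, 1, 1, 1,
             -1, -1, -1, -1, -1,
             0, 0, 0),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic matched MR/histology cohort
#'
#' One row per section. Collagen (picrosirius-red percent area) is drawn
#' uniformly over a wide fibrosis range; each collagen-coupled MR parameter
#' is a linear function of the standardised collagen value with the
#' physiological sign (positive for `ka`, `delta`, `MTR`, `f`, `fDstar`;
#' negative for `T1`, `T1s`, `ADC`, `D`, `T2long`) plus Gaussian scatter
#' calibrated so the expected sample correlation magnitude equals the
#' requested `collagenMtR`. `T2short`, `Dstar` and `ratio` are uncorrelated
#' fillers, as are the pimonidazole (hypoxia), microvessel-density and
#' necrosis covariates. Identical seeds give identical tables.
#'
#' @param spec a [CohortSpec-class].
#' @return A `data.frame` with `sectionId`, the 13 MR parameters, and
#'   `necrosis`, `mvd`, `pimonidazole`, `picrosirius` histology columns.
#' @examples
#' head(makeCohort(cohortSpec(nSections = 8, seed = 2)), 3)
#' @export
makeCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  n <- spec@nSections
  rho <- spec@collagenMtR
  tab <- cohortParamTable()

  withSeed(spec@seed, {
    collagen <- stats::runif(n, 5, 80)
    zx <- as.numeric(scale(collagen))
    out <- data.frame(sectionId = seq_len(n))
    for (i in seq_len(nrow(tab))) {
      s <- tab$sign[i]
      zy <- if (s == 0) stats::rnorm(n)
            else s * rho * zx +
                 spec@noiseSd * sqrt(1 - rho^2) * stats::rnorm(n)
      out[[tab$param[i]]] <- tab$mean[i] + tab$sd[i] * zy
    }
    out$necrosis <- pmin(pmax(stats::rnorm(n, 15, 10), 0), 60)
    out$mvd <- pmax(stats::rnorm(n, 80, 30), 1)
    out$pimonidazole <- pmax(stats::rnorm(n, 20, 8), 0.1)
    out$picrosirius <- collagen
    out
  })
}

#' Matched-section count from a cohort composition
#'
#' The number of matched MR/histology data sets implied by a study
#' composition in which every tumour yields one section except a subset of
#' large tumours sectioned in two places:
#' `tumours = tumourBearingRats + extraSimultaneousTumours`, and
#' `sections = tumours + twiceSectionedTumours`.
#'
#' @param tumourBearingRats rats contributing an analysable tumour.
#' @param extraSimultaneousTumours additional tumours in rats that grew
#'   more than one.
#' @param twiceSectionedTumours tumours sectioned in two places.
#' @return Integer section count.
#' @examples
#' countMatchedSections(13, 1, 4)  # 18
#' @export
countMatchedSections <- function(tumourBearingRats, extraSimultaneousTumours = 0L,
                                 twiceSectionedTumours = 0L) {
  stopifnot(tumourBearingRats >= 0, extraSimultaneousTumours >= 0,
            twiceSectionedTumours >= 0)
  as.integer(tumourBearingRats + extraSimultaneousTumours +
             twiceSectionedTumours)
}
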