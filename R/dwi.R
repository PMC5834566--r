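## Diffusion parameter estimation: perfusion-insensitive ADC, full IVIM
## with segmented initialisation, and the compound parameter f*D*.

#' Perfusion-insensitive ADC from the high-b regime
#'
#' Mono-exponential fit restricted to b >= 200 s/mm^2 (inclusive), where the
#' pseudo-diffusion pool has decayed away. Fitted in closed form by weighted
#' log-linear regression (weights = squared signal) for determinism; falls
#' back to bounded nonlinear least squares if any qualifying signal is
#' non-positive.
#'
#' @param signal observed magnitudes, one per b-value.
#' @param bvalues b-values in s/mm^2.
#' @param bmin lower edge of the qualifying regime (inclusive).
#' @return Named numeric `c(S0, ADC)`: the extrapolated b = 0 intercept and
#'   the apparent diffusion coefficient (mm^2/s).
#' @examples
#' b <- defaultBValues()
#' fitAdc(1000 * exp(-b * 1e-3), b)
#' @export
fitAdc <- function(signal, bvalues, bmin = 200) {
  if (length(signal) != length(bvalues))
    stop("signal and bvalues must have equal length", call. = FALSE)
  keep <- bvalues >= bmin
  if (sum(keep) < 2L)
    stop("need at least two b-values >= ", bmin, call. = FALSE)
  b <- bvalues[keep]
  y <- signal[keep]
  fit <- logLinearExpFit(b, y)
  if (is.null(fit)) {
    m <- modelSpec("monoexp_adc")
    fr <- nllsFit(m, b, y, init = c(max(max(y), 1), 1e-3))
    fit <- c(A = unname(fr@estimate["S0"]), k = unname(fr@estimate["ADC"]))
  }
  c(S0 = unname(fit[["A"]]), ADC = unname(fit[["k"]]))
}

#' Full IVIM fit with segmented initialisation
#'
#' Four-parameter bi-exponential fit of
#' `S_b = S0 (f exp(-b D*) + (1 - f) exp(-b D))` over all b-values.
#' Starting values follow the segmented approach: `D` and the intercept
#' from the b >= 200 mono-exponential ([fitAdc()]), and the initial
#' pseudo-diffusion fraction from the measured b = 0 signal relative to
#' that intercept, `f0 = (S(0) - intercept) / S(0)` clipped to \[0, 1\].
#' The simultaneous fit then runs through the chosen engine. If the fitted
#' `D*` falls below `D` the two pools are exchanged (`f` becomes `1 - f`)
#' so the pseudo-diffusion pool is always the fast one. `fDstar` is the
#' exact product of the final `f` and `Dstar`.
#'
#' @param signal observed magnitudes, one per b-value.
#' @param bvalues b-values including 0 and at least two values >= 200.
#' @param engine `"nlls"` or `"mcmc"`.
#' @param chainLength,burnIn,seed MCMC settings.
#' @return Named numeric `c(S0, ADC, f, D, Dstar, fDstar)`.
#' @examples
#' b <- defaultBValues()
#' s <- 1000 * (0.1 * exp(-b * 10e-3) + 0.9 * exp(-b * 1e-3))
#' round(fitIvim(s, b), 6)
#' @export
fitIvim <- function(signal, bvalues, engine = c("nlls", "mcmc"),
                    chainLength = 5000L, burnIn = 1000L, seed = 1L) {
  engine <- match.arg(engine)
  if (length(signal) != length(bvalues))
    stop("signal and bvalues must have equal length", call. = FALSE)
  if (!any(bvalues == 0))
    stop("bvalues must include b = 0", call. = FALSE)
  if (sum(bvalues >= 200) < 2L)
    stop("need at least two b-values >= 200", call. = FALSE)
  s0obs <- signal[which(bvalues == 0)[1L]]
  if (s0obs <= 0) stop("signal at b = 0 must be positive", call. = FALSE)
  adc <- fitAdc(signal, bvalues)
  if (adc[["ADC"]] <= 0)
    stop("high-b signal does not decay; refusing to fit catastrophic input",
         call. = FALSE)

  model <- modelSpec("ivim")
  f0 <- clip01((s0obs - adc[["S0"]]) / s0obs)
  init <- c(S0 = s0obs,
            f = min(max(f0, 1e-3), 1 - 1e-3),
            D = min(max(adc[["ADC"]], model@lower[3]), model@upper[3]),
            Dstar = min(max(10 * adc[["ADC"]], model@lower[4]),
                        model@upper[4]))
  fit <- if (engine == "nlls") nllsFit(model, bvalues, signal, init)
         else mcmcFit(model, bvalues, signal, init, chainLength, burnIn, seed)
  est <- fit@estimate
  if (est[["Dstar"]] < est[["D"]]) {  # exchange degeneracy: keep D* fast
    est[c("D", "Dstar")] <- est[c("Dstar", "D")]
    est[["f"]] <- 1 - est[["f"]]
  }
  c(S0 = est[["S0"]], ADC = adc[["ADC"]], f = est[["f"]], D = est[["D"]],
    Dstar = est[["Dstar"]], fDstar = est[["f"]] * est[["Dstar"]])
}

#' Voxel-wise IVIM parameter maps
#'
#' Runs [fitIvim()] in every mask voxel of a DWI stack and assembles maps
#' for `S0`, `ADC`, `f`, `D`, `Dstar` and `fDstar` (`NA` outside the mask).
#'
#' @param stack a [SignalStack-class] with DWI acquisition metadata.
#' @param mask logical 3D array matching the stack's spatial dimensions.
#' @param engine `"nlls"` or `"mcmc"`.
#' @param chainLength,burnIn,seed MCMC settings; each voxel's seed is
#'   derived from `seed` and its grid position.
#' @return A [ParameterMaps-class].
#' @export
ivimMaps <- function(stack, mask, engine = c("nlls", "mcmc"),
                     chainLength = 5000L, burnIn = 1000L, seed = 1L) {
  stopifnot(is(stack, "SignalStack"))
  engine <- match.arg(engine)
  if (stack@acquisition@modality != "dwi" ||
      !length(stack@acquisition@bvalues))
    stop("stack does not carry DWI b-value metadata", call. = FALSE)
  b <- stack@acquisition@bvalues
  dims <- dim(stack@signal)[1:3]
  if (!identical(dim(mask), dims))
    stop("mask dimensions must match the stack", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  sig2d <- matrix(stack@signal, ncol = length(b))
  pn <- c("S0", "ADC", "f", "D", "Dstar", "fDstar")
  maps <- lapply(pn, function(p) array(NA_real_, dim = dims))
  names(maps) <- pn
  for (v in which(mask)) {
    est <- fitIvim(sig2d[v, ], b, engine, chainLength, burnIn,
                   seed = (as.numeric(seed) * 1000003 + v) %% 2147483647)
    for (p in pn) maps[[p]][v] <- est[[p]]
  }
  parameterMaps(maps)
}
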