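## Dual-regime T2* estimation from ultrashort and conventional echoes.

#' Partition echo times into ultrashort and conventional regimes
#'
#' Echoes below 1 ms belong to the ultrashort regime; echoes at or above
#' 1 ms are conventional (the 1.0 ms boundary itself is conventional).
#'
#' @param echoTimes positive echo times in ms.
#' @return A list with elements `ultrashort` and `conventional`.
#' @examples
#' splitEchoes(defaultEchoTimes())
#' @export
splitEchoes <- function(echoTimes) {
  stopifnotPositive(echoTimes, "echo times")
  us <- echoTimes[echoTimes < 1]
  conv <- echoTimes[echoTimes >= 1]
  if (!length(us))
    stop("no ultrashort (< 1 ms) echoes present", call. = FALSE)
  if (!length(conv))
    stop("no conventional (>= 1 ms) echoes present", call. = FALSE)
  list(ultrashort = us, conventional = conv)
}

fitMonoExp <- function(x, y) {
  fit <- logLinearExpFit(x, y)
  if (!is.null(fit)) return(fit)
  m <- modelSpec("t2star")
  fr <- nllsFit(m, x, pmax(y, 0),
                init = c(max(max(y), 1), max(stats::median(x), 1e-2)))
  c(A = unname(fr@estimate["S0"]), k = 1 / unname(fr@estimate["T2star"]))
}

#' Two-regime T2* fit of one voxel
#'
#' The long-lived pool is fitted first, by a mono-exponential over the
#' conventional (>= 1 ms) echoes only. Its extrapolation is then subtracted
#' from the ultrashort (< 1 ms) echoes - over which the long pool is
#' essentially constant and would otherwise swamp the fast decay - and the
#' short-lived pool is fitted by a second mono-exponential on the residual.
#' The short-pool signal share, analogous to the IVIM pseudo-diffusion
#' fraction, is `ratio = (S0s - S0l) / S0s` clipped to \[0, 1\], where
#' `S0s` is the total TE -> 0 amplitude and `S0l` the long-pool amplitude.
#'
#' Fits use closed-form weighted log-linear regression with a bounded
#' nonlinear fallback when signals are non-positive. If the residual short
#' pool is everywhere non-positive there is no detectable short component:
#' `ratio` is 0 and `T2short` is `NA`.
#'
#' @param signal observed magnitudes, one per echo.
#' @param echoTimes echo times in ms with at least two echoes per regime.
#' @return Named numeric `c(T2short, T2long, S0s, S0l, ratio)`.
#' @examples
#' te <- defaultEchoTimes()
#' s <- 200 * exp(-te / 0.5) + 800 * exp(-te / 20)
#' round(fitUte(s, te), 4)
#' @export
fitUte <- function(signal, echoTimes) {
  if (length(signal) != length(echoTimes))
    stop("signal and echoTimes must have equal length", call. = FALSE)
  reg <- splitEchoes(echoTimes)
  if (length(reg$ultrashort) < 2L || length(reg$conventional) < 2L)
    stop("need at least two echoes in each regime", call. = FALSE)
  usIdx <- echoTimes < 1
  longFit <- fitMonoExp(echoTimes[!usIdx], signal[!usIdx])
  s0l <- longFit[["A"]]
  t2long <- 1 / longFit[["k"]]
  resid <- signal[usIdx] - s0l * exp(-echoTimes[usIdx] * longFit[["k"]])
  if (all(resid <= 0)) {
    return(c(T2short = NA_real_, T2long = t2long, S0s = s0l, S0l = s0l,
             ratio = 0))
  }
  shortFit <- fitMonoExp(echoTimes[usIdx], resid)
  amp <- shortFit[["A"]]
  s0s <- s0l + amp
  c(T2short = 1 / shortFit[["k"]], T2long = t2long, S0s = s0s, S0l = s0l,
    ratio = clip01(amp / s0s))
}

#' Voxel-wise dual-regime T2* maps
#'
#' Runs [fitUte()] in every mask voxel of a UTE stack; maps for `T2short`,
#' `T2long`, `S0s`, `S0l` and `ratio` (`NA` outside the mask).
#'
#' @param stack a [SignalStack-class] with UTE echo-time metadata.
#' @param mask logical 3D array matching the stack's spatial dimensions.
#' @return A [ParameterMaps-class].
#' @export
uteMaps <- function(stack, mask) {
  stopifnot(is(stack, "SignalStack"))
  if (stack@acquisition@modality != "ute" ||
      !length(stack@acquisition@echoTimes))
    stop("stack does not carry UTE echo-time metadata", call. = FALSE)
  te <- stack@acquisition@echoTimes
  dims <- dim(stack@signal)[1:3]
  if (!identical(dim(mask), dims))
    stop("mask dimensions must match the stack", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  sig2d <- matrix(stack@signal, ncol = length(te))
  pn <- c("T2short", "T2long", "S0s", "S0l", "ratio")
  maps <- lapply(pn, function(p) array(NA_real_, dim = dims))
  names(maps) <- pn
  for (v in which(mask)) {
    est <- fitUte(sig2d[v, ], te)
    for (p in pn) maps[[p]][v] <- est[[p]]
  }
  parameterMaps(maps)
}
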