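## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream (the global .Random.seed is saved and restored).
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

clip01 <- function(x) pmin(1, pmax(0, x))

stopifnotPositive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(what, " must be strictly positive", call. = FALSE)
  invisible(x)
}

## Spoiled gradient-echo steady-state signal (unit amplitude handled by S0).
## alpha in radians, tr and t1 in the same time unit.
spgrSignal <- function(S0, alpha, tr, t1) {
  E1 <- exp(-tr / t1)
  S0 * sin(alpha) * (1 - E1) / (1 - E1 * cos(alpha))
}

## Log-linear mono-exponential fit S = A * exp(-x / tau) (tau parameterised
## as rate k = 1/tau when `rate = TRUE`). Weighted by squared signal so the
## log-domain fit approximates least squares in the signal domain; exact for
## noiseless data either way. Returns c(A, k) with S = A * exp(-k * x).
logLinearExpFit <- function(x, y, weighted = TRUE) {
  if (any(y <= 0)) return(NULL)  # log undefined; caller falls back
  w <- if (weighted) y^2 else rep(1, length(y))
  fit <- stats::lm.wfit(cbind(1, x), log(y), w)
  k <- -fit$coefficients[2L]
  c(A = exp(fit$coefficients[1L]), k = unname(k))
}
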