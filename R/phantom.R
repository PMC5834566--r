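## Synthetic phantom generation and multi-modal forward signal simulation.

#' Default acquisition designs
#'
#' The default protocol mirrored by the simulators: nine diffusion b-values
#' 0-800 s/mm^2, four ultrashort (0.07-0.56 ms) plus four conventional
#' (7.16-20.60 ms) gradient echoes, and a two-flip-angle (4 deg / 24 deg)
#' spoiled gradient-echo MT acquisition at TR = 15 ms.
#'
#' @return Numeric vector (or scalar) of design values.
#' @name defaultDesigns
NULL

#' @rdname defaultDesigns
#' @export
defaultBValues <- function() c(0, 20, 40, 60, 80, 100, 200, 400, 800)

#' @rdname defaultDesigns
#' @export
defaultEchoTimes <- function() c(0.07, 0.14, 0.28, 0.56,
                                 7.16, 11.64, 16.12, 20.60)

#' @rdname defaultDesigns
#' @export
defaultMtTr <- function() 0.015

#' @rdname defaultDesigns
#' @export
defaultMtFlipAngles <- function() c(4, 24)

#' Default ground-truth parameter ranges
#'
#' Per-parameter `c(low, high)` bounds used by [makePhantom()] when drawing
#' piecewise-constant region values. Values are typical of soft-tissue
#' tumour at 1.5 T: diffusivities in mm^2/s, T2* in ms, T1 in s, and the
#' short-pool T2* centred on the ~0.5 ms relaxation of collagen.
#'
#' @return Named list of two-element numeric ranges.
#' @export
defaultParameterRanges <- function() {
  list(
    S0      = c(800, 1200),
    f       = c(0.05, 0.30),
    D       = c(0.5e-3, 1.5e-3),
    Dstar   = c(5e-3, 50e-3),
    T2short = c(0.30, 0.60),
    T2long  = c(15, 30),
    ratio   = c(0.10, 0.30),
    T1      = c(0.8, 1.6),
    MTR     = c(0.10, 0.40)
  )
}

#' Construct a PhantomSpec
#'
#' @param gridShape voxel counts per axis (length 3).
#' @param nRegions number of piecewise-constant tissue regions.
#' @param parameterRanges named list of `c(low, high)` draws; defaults from
#'   [defaultParameterRanges()] are used for any parameter not supplied.
#' @param noiseSigma Rician noise scale in signal units.
#' @param seed integer RNG seed.
#' @return A [PhantomSpec-class].
#' @examples
#' phantomSpec(c(12, 12, 4), nRegions = 3, seed = 7)
#' @export
phantomSpec <- function(gridShape = c(16, 16, 4), nRegions = 3L,
                        parameterRanges = list(), noiseSigma = 0,
                        seed = 1L) {
  ranges <- utils::modifyList(defaultParameterRanges(),
                              lapply(parameterRanges, as.numeric))
  new("PhantomSpec", gridShape = as.integer(gridShape),
      nRegions = as.integer(nRegions), parameterRanges = ranges,
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

## Effective per-TR saturation of the longitudinal magnetisation by the MT
## pulse, solved so that the steady-state MTR at the small nominal flip
## angle equals `mtr`. Inverts the saturated-SPGR steady state
##   S_MT = S0 sin(a) (1 - E1) / (1 - E1 (1 - dsat) cos(a)).
dsatFromMtr <- function(mtr, t1, tr, alphaNom) {
  E1c <- exp(-tr / t1) * cos(alphaNom)
  1 - (1 - (1 - E1c) / (1 - mtr)) / E1c
}

#' Generate a piecewise-constant ground-truth phantom
#'
#' Draws `nRegions` tissue regions (a background slab plus seeded random
#' ellipsoids inside a central tumour ROI), assigns each region one uniform
#' draw per drawable parameter (`S0`, `f`, `D`, `Dstar`, `T2short`,
#' `T2long`, `ratio`, `T1`, `MTR`), and derives the remaining maps so the
#' internal identities hold in every voxel:
#' `ADC` is the estimand of a weighted log-linear mono-exponential fit of
#' the noiseless bi-exponential diffusion signal at b >= 200; `T1s` follows
#' from the MT saturation implied by `MTR` and `T1` at the MT repetition
#' time; `ka = MTR / T1s`; and `delta = (TR/T1 + alpha^2/2) * MTR/(1-MTR)`,
#' the value the small-flip MT saturation estimator recovers from noiseless
#' data. Identical seeds give bit-identical phantoms.
#'
#' @param spec a [PhantomSpec-class].
#' @param mtTr MT repetition time (s) assumed for the derived MT maps.
#' @param mtAlphaNom nominal small flip angle (radians).
#' @return A [GroundTruth-class].
#' @examples
#' gt <- makePhantom(phantomSpec(c(8, 8, 2), nRegions = 2, seed = 7))
#' mapNames(gt)
#' @export
makePhantom <- function(spec, mtTr = defaultMtTr(),
                        mtAlphaNom = defaultMtFlipAngles()[1] * pi / 180) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  dims <- spec@gridShape
  nr <- spec@nRegions

  withSeed(spec@seed, {
    ## central ellipsoidal ROI ("tumour") with random internal ellipsoids
    ax <- lapply(dims, function(n) (seq_len(n) - (n + 1) / 2) / (n / 2))
    grid <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
    roi <- array((grid$x / 0.95)^2 + (grid$y / 0.95)^2 + (grid$z / 0.95)^2 <= 1,
                 dim = dims)
    if (!any(roi)) roi[] <- TRUE  # degenerate tiny grids
    labels <- array(1L, dim = dims)
    if (nr > 1L) {
      for (r in 2:nr) {
        repeat {
          ctr <- stats::runif(3, -0.4, 0.4)
          sem <- stats::runif(3, 0.15, 0.45)
          inside <- ((grid$x - ctr[1]) / sem[1])^2 +
                    ((grid$y - ctr[2]) / sem[2])^2 +
                    ((grid$z - ctr[3]) / sem[3])^2 <= 1
          inside <- array(inside, dim = dims) & roi
          if (any(inside)) { labels[inside] <- r; break }
        }
      }
      ## regions can be fully overwritten by later ones; relabel compactly
      present <- sort(unique(as.vector(labels)))
      labels <- array(match(labels, present), dim = dims)
      nr <- length(present)
    }

    rng <- spec@parameterRanges
    draw <- function(p) stats::runif(nr, rng[[p]][1], rng[[p]][2])
    vals <- list(S0 = draw("S0"), f = draw("f"), D = draw("D"),
                 Dstar = draw("Dstar"), T2short = draw("T2short"),
                 T2long = draw("T2long"), ratio = draw("ratio"),
                 T1 = draw("T1"), MTR = draw("MTR"))
    ## pseudo-diffusion must stay the fast pool
    vals$Dstar <- pmax(vals$Dstar, vals$D * 1.05)

    ## derived: ADC estimand at the high-b subset of the default protocol
    bHigh <- defaultBValues()[defaultBValues() >= 200]
    vals$ADC <- vapply(seq_len(nr), function(r) {
      s <- vals$S0[r] * (vals$f[r] * exp(-bHigh * vals$Dstar[r]) +
                         (1 - vals$f[r]) * exp(-bHigh * vals$D[r]))
      logLinearExpFit(bHigh, s)[["k"]]
    }, 0)
    dsat <- dsatFromMtr(vals$MTR, vals$T1, mtTr, mtAlphaNom)
    E1 <- exp(-mtTr / vals$T1)
    vals$T1s <- -mtTr / log(E1 * (1 - dsat))
    vals$ka <- vals$MTR / vals$T1s
    vals$delta <- (mtTr / vals$T1 + mtAlphaNom^2 / 2) *
      vals$MTR / (1 - vals$MTR)

    maps <- lapply(vals, function(v) array(v[labels], dim = dims))
    new("GroundTruth", maps = parameterMaps(maps), roi = roi,
        regions = labels, mtTr = mtTr, mtAlphaNom = mtAlphaNom)
  })
}

#' Simulate a diffusion-weighted acquisition
#'
#' Noiseless bi-exponential intravoxel-incoherent-motion signal
#' `S_b = S0 * (f * exp(-b D*) + (1 - f) * exp(-b D))` at each b-value.
#'
#' @param gt a [GroundTruth-class] phantom.
#' @param bvalues non-negative, strictly increasing b-values (s/mm^2).
#' @return A [SignalStack-class] carrying a DWI [AcquisitionSpec-class].
#' @export
simulateDwi <- function(gt, bvalues = defaultBValues()) {
  stopifnot(is(gt, "GroundTruth"))
  if (any(bvalues < 0)) stop("b-values must be non-negative", call. = FALSE)
  if (is.unsorted(bvalues, strictly = TRUE))
    stop("b-values must be strictly increasing (no duplicates)", call. = FALSE)
  m <- gt@maps@maps
  dims <- dim(m$S0)
  sig <- vapply(bvalues, function(b) {
    m$S0 * (m$f * exp(-b * m$Dstar) + (1 - m$f) * exp(-b * m$D))
  }, m$S0)
  signalStack(array(sig, dim = c(dims, length(bvalues))),
              acquisitionSpec("dwi", bvalues = bvalues))
}

#' Simulate an ultrashort-echo multi-gradient-echo acquisition
#'
#' Two-pool forward model: a short-lived pool of amplitude `S0 * ratio`
#' decaying with `T2short` plus a long-lived pool of amplitude
#' `S0 * (1 - ratio)` decaying with `T2long`, so the total TE -> 0 amplitude
#' is `S0` and the short-pool signal share equals the ground-truth `ratio`.
#'
#' @param gt a [GroundTruth-class] phantom.
#' @param echoTimes positive echo times in ms.
#' @return A [SignalStack-class] carrying a UTE [AcquisitionSpec-class].
#' @export
simulateUte <- function(gt, echoTimes = defaultEchoTimes()) {
  stopifnot(is(gt, "GroundTruth"))
  stopifnotPositive(echoTimes, "echo times")
  m <- gt@maps@maps
  dims <- dim(m$S0)
  s0s <- m$S0
  s0l <- m$S0 * (1 - m$ratio)
  sig <- vapply(echoTimes, function(te) {
    (s0s - s0l) * exp(-te / m$T2short) + s0l * exp(-te / m$T2long)
  }, m$S0)
  signalStack(array(sig, dim = c(dims, length(echoTimes))),
              acquisitionSpec("ute", echoTimes = echoTimes))
}

#' Simulate the four-volume magnetisation-transfer acquisition
#'
#' Produces two flip angles each without and with the MT saturation pulse.
#' Without-MT volumes follow the spoiled gradient-echo steady state with
#' `T1`. With-MT volumes follow the saturated steady state
#' `S = S0 sin(a) (1 - E1) / (1 - E1 (1 - dsat) cos(a))` - algebraically an
#' SPGR curve with relaxation `T1s` and a constant amplitude rescale - with
#' the per-TR saturation `dsat` solved per voxel so the MTR measured at the
#' small flip angle equals the ground-truth MTR map.
#'
#' A transmit-field error multiplier `b1` scales the actual readout flip
#' angles by `b1` and the saturation by `b1^2` (saturation is quadratic in
#' pulse amplitude); it exists to probe the relative B1 sensitivity of MTR
#' and the MT saturation estimate and defaults to a perfect field.
#'
#' @param gt a [GroundTruth-class] phantom.
#' @param tr repetition time in seconds.
#' @param flipAngles exactly two nominal flip angles in degrees.
#' @param b1 transmit field multiplier (1 = nominal).
#' @return A [SignalStack-class] with volumes ordered
#'   (flip1 ref, flip2 ref, flip1 MT, flip2 MT).
#' @export
simulateMt <- function(gt, tr = defaultMtTr(),
                       flipAngles = defaultMtFlipAngles(), b1 = 1) {
  stopifnot(is(gt, "GroundTruth"))
  stopifnotPositive(tr, "tr")
  if (length(flipAngles) != 2L)
    stop("exactly two flip angles are required", call. = FALSE)
  if (any(flipAngles <= 0 | flipAngles >= 90))
    stop("flip angles must lie strictly between 0 and 90 degrees",
         call. = FALSE)
  m <- gt@maps@maps
  dims <- dim(m$S0)
  alphaNom <- sort(flipAngles) * pi / 180
  alphaAct <- b1 * alphaNom
  dsat <- dsatFromMtr(m$MTR, m$T1, tr, alphaNom[1]) * b1^2
  E1 <- exp(-tr / m$T1)
  vols <- c(
    lapply(alphaAct, function(a) spgrSignal(m$S0, a, tr, m$T1)),
    lapply(alphaAct, function(a) {
      m$S0 * sin(a) * (1 - E1) / (1 - E1 * (1 - dsat) * cos(a))
    })
  )
  signalStack(array(unlist(vols), dim = c(dims, 4L)),
              acquisitionSpec("mt", tr = tr,
                              flipAngles = rep(sort(flipAngles), 2L),
                              mtPulse = c(FALSE, FALSE, TRUE, TRUE)))
}

#' Add magnitude noise to a signal stack
#'
#' Rician noise as arises on magnitude MR images:
#' `sqrt((S + n1)^2 + n2^2)` with `n1`, `n2` independent zero-mean Gaussians
#' of scale `sigma`. A plain additive Gaussian mode is available for unit
#' tests of estimator behaviour without the Rician floor. `sigma = 0`
#' returns the input unchanged.
#'
#' @param stack a [SignalStack-class].
#' @param sigma noise scale in signal units, non-negative.
#' @param seed integer RNG seed.
#' @param type `"rician"` (default) or `"gaussian"`.
#' @return A [SignalStack-class] with the same acquisition metadata.
#' @export
addNoise <- function(stack, sigma, seed = 1L,
                     type = c("rician", "gaussian")) {
  stopifnot(is(stack, "SignalStack"))
  type <- match.arg(type)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (sigma == 0) return(stack)
  s <- stack@signal
  withSeed(seed, {
    if (type == "rician") {
      n1 <- array(stats::rnorm(length(s), 0, sigma), dim = dim(s))
      n2 <- array(stats::rnorm(length(s), 0, sigma), dim = dim(s))
      s <- sqrt((s + n1)^2 + n2^2)
    } else {
      s <- s + array(stats::rnorm(length(s), 0, sigma), dim = dim(s))
    }
  })
  signalStack(s, stack@acquisition)
}
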