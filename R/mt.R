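## Magnetisation-transfer parameter estimation: variable-flip-angle T1,
## MTR, apparent MT rate ka, and B1-insensitive MT saturation delta.

#' Two-point variable-flip-angle T1
#'
#' Closed-form solution of the spoiled gradient-echo steady state from two
#' flip angles: regressing `S / sin(a)` on `S / tan(a)` gives a slope
#' `m = exp(-TR / T1)`, hence `T1 = -TR / log(m)` and the amplitude from
#' the intercept. Scale-invariant in the signals. Voxels with a
#' non-physical slope (`m <= 0` or `m >= 1`, e.g. pure noise) are flagged:
#' their `T1` and `S0` are `NA`.
#'
#' All arguments are vectorised over voxels.
#'
#' @param sLow,sHigh signals at the lower and higher flip angle.
#' @param flips the two flip angles in degrees, `c(low, high)`.
#' @param tr repetition time in seconds.
#' @return A list with numeric `T1` (s), `S0`, and logical `flagged`.
#' @examples
#' a <- c(4, 24) * pi / 180
#' s <- 850 * sin(a) * (1 - exp(-0.0125)) / (1 - exp(-0.0125) * cos(a))
#' vfaT1(s[1], s[2], c(4, 24), 0.015)  # recovers T1 = 1.2 s
#' @export
vfaT1 <- function(sLow, sHigh, flips = defaultMtFlipAngles(),
                  tr = defaultMtTr()) {
  if (length(flips) != 2L || flips[1] == flips[2])
    stop("two distinct flip angles are required", call. = FALSE)
  stopifnotPositive(tr, "tr")
  a <- flips * pi / 180
  y1 <- sLow / sin(a[1]);  x1 <- sLow / tan(a[1])
  y2 <- sHigh / sin(a[2]); x2 <- sHigh / tan(a[2])
  m <- (y2 - y1) / (x2 - x1)
  flagged <- !is.finite(m) | m <= 0 | m >= 1
  t1 <- ifelse(flagged, NA_real_, -tr / log(m))
  s0 <- ifelse(flagged, NA_real_, (y1 - m * x1) / (1 - m))
  list(T1 = t1, S0 = s0, flagged = flagged)
}

#' Magnetisation transfer ratio
#'
#' `MTR = (Sref - Smt) / Sref`, the fractional signal destroyed by the MT
#' pulse. Noise can push the raw value slightly negative or above 1; values
#' are clipped to \[-0.05, 1\] and clip events reported via a message
#' rather than discarded (no data filtering). Vectorised.
#'
#' @param sRef signal without the MT pulse (must be positive).
#' @param sMt signal with the MT pulse.
#' @return Numeric MTR values.
#' @examples
#' computeMtr(1000, 700)
#' @export
computeMtr <- function(sRef, sMt) {
  if (any(sRef <= 0)) stop("sRef must be positive", call. = FALSE)
  mtr <- (sRef - sMt) / sRef
  nClip <- sum(mtr < -0.05 | mtr > 1)
  if (nClip > 0)
    message("computeMtr: clipped ", nClip, " value(s) to [-0.05, 1]")
  pmin(1, pmax(-0.05, mtr))
}

#' Apparent magnetisation-transfer rate
#'
#' `ka = MTR / T1s` (1/s): an empirical rate constant for the destruction
#' of water signal by the MT saturation, normalising the MT ratio by the
#' saturated longitudinal relaxation time. Vectorised.
#'
#' @param mtr magnetisation transfer ratio.
#' @param t1s longitudinal relaxation time with the MT pulse, in seconds.
#' @return Numeric ka in 1/s.
#' @examples
#' computeKa(0.3, 0.5)
#' @export
computeKa <- function(mtr, t1s) {
  if (any(t1s <= 0, na.rm = TRUE)) stop("t1s must be positive", call. = FALSE)
  mtr / t1s
}

#' B1-insensitive magnetisation-transfer saturation
#'
#' `delta = (R1app * TR + alpha^2 / 2) * (Sref - Smt) / Smt`, evaluated at
#' the small-flip-angle acquisition pair with the nominal flip angle in
#' radians. Under a transmit-field error the readout-flip bias of the
#' signal ratio and the bias of the apparent relaxation rate cancel in the
#' small-angle regime, making delta far less B1-dependent than MTR.
#' Vectorised.
#'
#' @param r1app apparent longitudinal relaxation rate 1/T1 (1/s), from the
#'   without-MT VFA fit.
#' @param tr repetition time in seconds.
#' @param alphaNom nominal flip angle in radians.
#' @param sRef,sMt signals without / with the MT pulse (`sMt` positive).
#' @return Numeric delta (dimensionless).
#' @examples
#' computeDelta(1.0, 0.015, 4 * pi / 180, 1000, 700)
#' @export
computeDelta <- function(r1app, tr, alphaNom, sRef, sMt) {
  if (any(sMt <= 0)) stop("sMt must be positive", call. = FALSE)
  (r1app * tr + alphaNom^2 / 2) * (sRef - sMt) / sMt
}

#' Voxel-wise magnetisation-transfer parameter maps
#'
#' From the four-volume MT acquisition (two flip angles, each without and
#' with the MT pulse): `T1` from the without-MT pair and `T1s` from the
#' with-MT pair (both closed-form VFA), then `MTR`, `ka = MTR / T1s` and
#' `delta` from the small-flip-angle pair with `R1app = 1 / T1`. The
#' high-flip acquisition serves the VFA fits only. All maps are closed
#' form, computed in every mask voxel (`NA` outside; VFA-flagged voxels
#' propagate `NA` into `T1`-dependent maps).
#'
#' @param stack a [SignalStack-class] with MT flip/pulse metadata
#'   (four volumes).
#' @param mask logical 3D array matching the stack's spatial dimensions.
#' @return A [ParameterMaps-class] with `T1`, `T1s`, `MTR`, `ka`, `delta`.
#' @export
mtMaps <- function(stack, mask) {
  stopifnot(is(stack, "SignalStack"))
  acq <- stack@acquisition
  if (acq@modality != "mt" || length(acq@flipAngles) != 4L)
    stop("stack must carry the four-volume MT acquisition metadata",
         call. = FALSE)
  dims <- dim(stack@signal)[1:3]
  if (!identical(dim(mask), dims))
    stop("mask dimensions must match the stack", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  flips <- sort(unique(acq@flipAngles))
  if (length(flips) != 2L)
    stop("expected exactly two distinct flip angles", call. = FALSE)
  volIdx <- function(flip, mt) {
    i <- which(acq@flipAngles == flip & acq@mtPulse == mt)
    if (length(i) != 1L)
      stop("missing or duplicated MT volume (flip ", flip,
           if (mt) " with" else " without", " MT pulse)", call. = FALSE)
    i
  }
  s <- stack@signal
  refLo <- s[, , , volIdx(flips[1], FALSE)]
  refHi <- s[, , , volIdx(flips[2], FALSE)]
  mtLo  <- s[, , , volIdx(flips[1], TRUE)]
  mtHi  <- s[, , , volIdx(flips[2], TRUE)]
  dim(refLo) <- dim(refHi) <- dim(mtLo) <- dim(mtHi) <- dims

  vRef <- vfaT1(refLo[mask], refHi[mask], flips, acq@tr)
  vMt <- vfaT1(mtLo[mask], mtHi[mask], flips, acq@tr)
  mtr <- computeMtr(refLo[mask], mtLo[mask])
  ka <- computeKa(mtr, ifelse(vMt$flagged, NA_real_, vMt$T1))
  delta <- computeDelta(1 / vRef$T1, acq@tr, flips[1] * pi / 180,
                        refLo[mask], pmax(mtLo[mask], .Machine$double.eps))

  pn <- c("T1", "T1s", "MTR", "ka", "delta")
  maps <- lapply(pn, function(p) array(NA_real_, dim = dims))
  names(maps) <- pn
  maps$T1[mask] <- vRef$T1
  maps$T1s[mask] <- vMt$T1
  maps$MTR[mask] <- mtr
  maps$ka[mask] <- ka
  maps$delta[mask] <- delta
  parameterMaps(maps)
}
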