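#' @import methods
NULL

#' Acquisition parameters for one MR modality
#'
#' Container for the acquisition metadata that a [SignalStack-class] carries
#' alongside its voxel data: diffusion b-values, echo times, repetition time,
#' flip angles and the per-volume magnetisation-transfer pulse state. Units
#' follow the conventions of the source protocol: b-values in s/mm^2
#' (reciprocal to the diffusivity unit mm^2/s), echo times in ms, repetition
#' time in s, flip angles in degrees.
#'
#' @slot modality character, one of `"dwi"`, `"ute"`, `"mt"`.
#' @slot bvalues numeric, diffusion weightings (DWI only).
#' @slot echoTimes numeric, echo times in ms (UTE only).
#' @slot tr numeric scalar, repetition time in seconds (MT only).
#' @slot flipAngles numeric, per-volume flip angle in degrees (MT only).
#' @slot mtPulse logical, per-volume MT saturation pulse state (MT only).
#'
#' @seealso [acquisitionSpec()], [SignalStack-class]
#' @export
setClass("AcquisitionSpec",
  representation(
    modality = "character",
    bvalues = "numeric",
    echoTimes = "numeric",
    tr = "numeric",
    flipAngles = "numeric",
    mtPulse = "logical"
  ),
  prototype(
    modality = NA_character_,
    bvalues = numeric(0),
    echoTimes = numeric(0),
    tr = NA_real_,
    flipAngles = numeric(0),
    mtPulse = logical(0)
  )
)

setValidity("AcquisitionSpec", function(object) {
  msg <- character(0)
  if (length(object@modality) != 1L ||
      !object@modality %in% c("dwi", "ute", "mt"))
    msg <- c(msg, "modality must be one of 'dwi', 'ute', 'mt'")
  if (length(object@bvalues) && any(object@bvalues < 0))
    msg <- c(msg, "b-values must be non-negative")
  if (length(object@bvalues) && is.unsorted(object@bvalues, strictly = TRUE))
    msg <- c(msg, "b-values must be strictly increasing (no duplicates)")
  if (length(object@echoTimes) && any(object@echoTimes <= 0))
    msg <- c(msg, "echo times must be positive")
  if (!is.na(object@tr) && object@tr <= 0)
    msg <- c(msg, "tr must be positive")
  if (length(object@flipAngles) &&
      any(object@flipAngles <= 0 | object@flipAngles >= 90))
    msg <- c(msg, "flip angles must lie strictly between 0 and 90 degrees")
  if (length(object@flipAngles) != length(object@mtPulse))
    msg <- c(msg, "flipAngles and mtPulse must have one entry per volume")
  if (length(msg)) msg else TRUE
})

#' Construct an AcquisitionSpec
#'
#' @param modality `"dwi"`, `"ute"` or `"mt"`.
#' @param bvalues diffusion b-values in s/mm^2, strictly increasing.
#' @param echoTimes echo times in ms.
#' @param tr repetition time in seconds.
#' @param flipAngles per-volume flip angles in degrees.
#' @param mtPulse per-volume logical MT pulse state.
#' @return An [AcquisitionSpec-class] object.
#' @examples
#' acquisitionSpec("dwi", bvalues = c(0, 20, 40, 60, 80, 100, 200, 400, 800))
#' @export
acquisitionSpec <- function(modality,
                            bvalues = numeric(0),
                            echoTimes = numeric(0),
                            tr = NA_real_,
                            flipAngles = numeric(0),
                            mtPulse = logical(0)) {
  new("AcquisitionSpec", modality = modality, bvalues = as.numeric(bvalues),
      echoTimes = as.numeric(echoTimes), tr = as.numeric(tr),
      flipAngles = as.numeric(flipAngles), mtPulse = as.logical(mtPulse))
}

#' 4D magnitude MR signal series with its acquisition metadata
#'
#' A `SignalStack` holds a 4D array of voxel magnitudes (x, y, z, volume)
#' together with the [AcquisitionSpec-class] describing what each volume is
#' (its b-value, echo time, or flip-angle/MT-pulse combination).
#'
#' @slot signal 4D numeric array, last dimension indexes volumes.
#' @slot acquisition an [AcquisitionSpec-class]; its design length must match
#'   the number of volumes.
#' @seealso [signalStack()], [fitVolume()]
#' @export
setClass("SignalStack",
  representation(signal = "array", acquisition = "AcquisitionSpec"))

designLength <- function(acq) {
  switch(acq@modality,
    dwi = length(acq@bvalues),
    ute = length(acq@echoTimes),
    mt  = length(acq@flipAngles),
    0L)
}

setValidity("SignalStack", function(object) {
  msg <- character(0)
  if (length(dim(object@signal)) != 4L)
    msg <- c(msg, "signal must be a 4D array (x, y, z, volume)")
  else if (dim(object@signal)[4L] != designLength(object@acquisition))
    msg <- c(msg, sprintf(
      "number of volumes (%d) does not match acquisition design (%d)",
      dim(object@signal)[4L], designLength(object@acquisition)))
  if (any(!is.finite(object@signal)))
    msg <- c(msg, "signal contains non-finite values")
  if (length(msg)) msg else TRUE
})

#' Construct a SignalStack
#'
#' @param signal 4D numeric array (x, y, z, volume).
#' @param acquisition matching [AcquisitionSpec-class].
#' @return A [SignalStack-class].
#' @export
signalStack <- function(signal, acquisition) {
  new("SignalStack", signal = signal, acquisition = acquisition)
}

#' Named voxel-wise parameter maps
#'
#' A thin container for a set of equally shaped 3D maps (one per model
#' parameter). Voxels outside the fitted mask carry `NA` sentinels.
#'
#' @slot maps named list of 3D numeric arrays, all with identical dimensions.
#' @seealso [paramMap()], [mapNames()]
#' @export
setClass("ParameterMaps", representation(maps = "list"))

setValidity("ParameterMaps", function(object) {
  msg <- character(0)
  if (length(object@maps)) {
    if (is.null(names(object@maps)) || any(names(object@maps) == ""))
      msg <- c(msg, "all maps must be named")
    dims <- lapply(object@maps, dim)
    if (any(vapply(dims, length, 0L) != 3L))
      msg <- c(msg, "each map must be a 3D array")
    else if (length(unique(dims)) > 1L)
      msg <- c(msg, "all maps must share the same dimensions")
  }
  if (length(msg)) msg else TRUE
})

#' Construct ParameterMaps from a named list of 3D arrays
#' @param maps named list of 3D numeric arrays of identical shape.
#' @return A [ParameterMaps-class].
#' @export
parameterMaps <- function(maps) new("ParameterMaps", maps = maps)

#' Ground-truth phantom: parameter maps plus tumour ROI
#'
#' Produced by [makePhantom()]; holds the full set of ground-truth voxel maps
#' (`S0`, `f`, `D`, `Dstar`, `ADC`, `T2short`, `T2long`, `ratio`, `T1`,
#' `T1s`, `MTR`, `ka`, `delta`), the binary tumour ROI, the integer region
#' labels, and the MT acquisition constants (repetition time, nominal small
#' flip angle) that the derived MT maps assume.
#'
#' @slot maps a [ParameterMaps-class] with the thirteen ground-truth maps.
#' @slot roi logical 3D array, the tumour mask.
#' @slot regions integer 3D array of piecewise-constant region labels.
#' @slot mtTr numeric, MT repetition time in s used to derive T1s/ka/delta.
#' @slot mtAlphaNom numeric, nominal small flip angle in radians.
#' @export
setClass("GroundTruth",
  representation(maps = "ParameterMaps", roi = "array", regions = "array",
                 mtTr = "numeric", mtAlphaNom = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  m <- object@maps@maps
  need <- c("S0", "f", "D", "Dstar", "ADC", "T2short", "T2long", "ratio",
            "T1", "T1s", "MTR", "ka", "delta")
  if (!all(need %in% names(m)))
    msg <- c(msg, paste("missing ground-truth maps:",
                        paste(setdiff(need, names(m)), collapse = ", ")))
  else {
    if (any(m$f < 0 | m$f > 1)) msg <- c(msg, "f must lie in [0, 1]")
    for (p in c("D", "Dstar", "T2short", "T2long", "T1", "T1s"))
      if (any(m[[p]] <= 0)) msg <- c(msg, paste(p, "must be strictly positive"))
    if (any(m$Dstar <= m$D))
      msg <- c(msg, "Dstar must exceed D in every voxel")
  }
  if (!identical(dim(object@roi), dim(m[[1L]])))
    msg <- c(msg, "roi dimensions must match the maps")
  if (length(msg)) msg else TRUE
})

#' Parametric signal model family for the fitting engine
#'
#' Describes one of the voxel-wise signal models: its ordered parameters,
#' finite box bounds, and a forward function mapping a parameter vector and
#' design points (b-values, echo times, or flip-angle index) to predicted
#' signal. Built-in families are created with [modelSpec()].
#'
#' @slot name model family name.
#' @slot parameterNames ordered parameter names.
#' @slot lower,upper finite per-parameter bounds, `lower < upper`.
#' @slot forward `function(params, design)` returning predicted signal.
#' @export
setClass("ModelSpec",
  representation(name = "character", parameterNames = "character",
                 lower = "numeric", upper = "numeric", forward = "function"))

setValidity("ModelSpec", function(object) {
  msg <- character(0)
  p <- length(object@parameterNames)
  if (length(object@lower) != p || length(object@upper) != p)
    msg <- c(msg, "bounds must have one entry per parameter")
  if (any(!is.finite(object@lower)) || any(!is.finite(object@upper)))
    msg <- c(msg, "bounds must be finite")
  if (any(object@lower >= object@upper))
    msg <- c(msg, "each lower bound must be below its upper bound")
  if (length(msg)) msg else TRUE
})

#' Per-voxel fit result
#'
#' Point estimates (posterior medians for the MCMC engine, least-squares
#' minimisers for the NLLS engine), a per-parameter spread (posterior
#' interquartile range; zero for NLLS), the residual sum of squares, the
#' sampler length and a convergence flag.
#'
#' @slot estimate named numeric, within the model bounds.
#' @slot spread named numeric, per-parameter posterior IQR.
#' @slot rss numeric, residual sum of squares at the point estimate.
#' @slot nIter integer, iterations/samples used.
#' @slot converged logical.
#' @export
setClass("FitResult",
  representation(estimate = "numeric", spread = "numeric", rss = "numeric",
                 nIter = "integer", converged = "logical"))

setValidity("FitResult", function(object) {
  msg <- character(0)
  if (length(object@rss) != 1L || is.na(object@rss) || object@rss < 0)
    msg <- c(msg, "rss must be a single non-negative number")
  if (length(object@estimate) != length(object@spread))
    msg <- c(msg, "estimate and spread must be the same length")
  if (length(msg)) msg else TRUE
})

#' Phantom generation settings
#'
#' @slot gridShape integer vector of voxel counts per axis.
#' @slot nRegions number of piecewise-constant tissue regions.
#' @slot parameterRanges named list of `c(low, high)` bounds for the drawable
#'   ground-truth parameters.
#' @slot noiseSigma Rician noise scale in signal units (applied by
#'   [addNoise()], recorded here for provenance).
#' @slot seed integer RNG seed.
#' @seealso [phantomSpec()], [makePhantom()]
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", nRegions = "integer",
                 parameterRanges = "list", noiseSigma = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be three strictly positive voxel counts")
  if (object@nRegions < 1L)
    msg <- c(msg, "nRegions must be at least 1")
  bad <- vapply(object@parameterRanges,
                function(r) length(r) != 2L || r[1L] > r[2L], FALSE)
  if (any(bad))
    msg <- c(msg, paste("inverted or malformed range for:",
                        paste(names(object@parameterRanges)[bad], collapse = ", ")))
  if (object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort settings
#'
#' @slot nSections number of matched MR/histology sections.
#' @slot collagenMtR target Pearson correlation magnitude between collagen
#'   fraction and the collagen-coupled MR parameters.
#' @slot noiseSd residual scatter multiplier (1 = calibrated to
#'   `collagenMtR`; 0 = noiseless lines).
#' @slot seed integer RNG seed.
#' @seealso [cohortSpec()], [makeCohort()]
#' @export
setClass("CohortSpec",
  representation(nSections = "integer", collagenMtR = "numeric",
                 noiseSd = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  if (object@nSections < 4L)
    msg <- c(msg, "nSections must be at least 4")
  if (abs(object@collagenMtR) >= 1)
    msg <- c(msg, "collagenMtR must lie strictly inside (-1, 1)")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be non-negative")
  if (length(msg)) msg else TRUE
})
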