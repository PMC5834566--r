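#' @include AllClasses.R
NULL

#' Accessors for fibromap S4 containers
#'
#' Small accessor family: `signalData()` returns the 4D voxel array of a
#' [SignalStack-class]; `acquisition()` its [AcquisitionSpec-class];
#' `bValues()`, `echoTimes()`, `repetitionTime()`, `flipAngles()` and
#' `mtPulse()` pull the corresponding design vectors; `mapNames()` and
#' `paramMap()` index a [ParameterMaps-class]; `roiMask()` returns the
#' ground-truth tumour mask; `estimate()`, `posteriorSpread()`,
#' `residualSS()` and `isConverged()` unpack a [FitResult-class].
#'
#' @param x the object.
#' @param name for `paramMap()`, the map to extract.
#' @return The extracted component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))
#' @rdname accessors
#' @export
setGeneric("acquisition", function(x) standardGeneric("acquisition"))
#' @rdname accessors
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))
#' @rdname accessors
#' @export
setGeneric("echoTimes", function(x) standardGeneric("echoTimes"))
#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))
#' @rdname accessors
#' @export
setGeneric("flipAngles", function(x) standardGeneric("flipAngles"))
#' @rdname accessors
#' @export
setGeneric("mtPulse", function(x) standardGeneric("mtPulse"))
#' @rdname accessors
#' @export
setGeneric("mapNames", function(x) standardGeneric("mapNames"))
#' @rdname accessors
#' @export
setGeneric("paramMap", function(x, name) standardGeneric("paramMap"))
#' @rdname accessors
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))
#' @rdname accessors
#' @export
setGeneric("estimate", function(x) standardGeneric("estimate"))
#' @rdname accessors
#' @export
setGeneric("posteriorSpread", function(x) standardGeneric("posteriorSpread"))
#' @rdname accessors
#' @export
setGeneric("residualSS", function(x) standardGeneric("residualSS"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname accessors
setMethod("signalData", "SignalStack", function(x) x@signal)
#' @rdname accessors
setMethod("acquisition", "SignalStack", function(x) x@acquisition)
#' @rdname accessors
setMethod("bValues", "AcquisitionSpec", function(x) x@bvalues)
#' @rdname accessors
setMethod("bValues", "SignalStack", function(x) x@acquisition@bvalues)
#' @rdname accessors
setMethod("echoTimes", "AcquisitionSpec", function(x) x@echoTimes)
#' @rdname accessors
setMethod("echoTimes", "SignalStack", function(x) x@acquisition@echoTimes)
#' @rdname accessors
setMethod("repetitionTime", "AcquisitionSpec", function(x) x@tr)
#' @rdname accessors
setMethod("repetitionTime", "SignalStack", function(x) x@acquisition@tr)
#' @rdname accessors
setMethod("flipAngles", "AcquisitionSpec", function(x) x@flipAngles)
#' @rdname accessors
setMethod("flipAngles", "SignalStack", function(x) x@acquisition@flipAngles)
#' @rdname accessors
setMethod("mtPulse", "AcquisitionSpec", function(x) x@mtPulse)
#' @rdname accessors
setMethod("mtPulse", "SignalStack", function(x) x@acquisition@mtPulse)
#' @rdname accessors
setMethod("mapNames", "ParameterMaps", function(x) names(x@maps))
#' @rdname accessors
setMethod("mapNames", "GroundTruth", function(x) names(x@maps@maps))
#' @rdname accessors
setMethod("paramMap", "ParameterMaps", function(x, name) {
  if (!name %in% names(x@maps))
    stop("no map named '", name, "'", call. = FALSE)
  x@maps[[name]]
})
#' @rdname accessors
setMethod("paramMap", "GroundTruth", function(x, name) paramMap(x@maps, name))
#' @rdname accessors
setMethod("roiMask", "GroundTruth", function(x) x@roi)
#' @rdname accessors
setMethod("estimate", "FitResult", function(x) x@estimate)
#' @rdname accessors
setMethod("posteriorSpread", "FitResult", function(x) x@spread)
#' @rdname accessors
setMethod("residualSS", "FitResult", function(x) x@rss)
#' @rdname accessors
setMethod("isConverged", "FitResult", function(x) x@converged)

setMethod("show", "AcquisitionSpec", function(object) {
  cat("AcquisitionSpec [", object@modality, "]\n", sep = "")
  if (length(object@bvalues))
    cat("  b-values (s/mm^2): ", paste(object@bvalues, collapse = ", "), "\n",
        sep = "")
  if (length(object@echoTimes))
    cat("  echo times (ms): ", paste(object@echoTimes, collapse = ", "), "\n",
        sep = "")
  if (!is.na(object@tr)) cat("  TR (s): ", object@tr, "\n", sep = "")
  if (length(object@flipAngles))
    cat("  volumes: ",
        paste(sprintf("%g°%s", object@flipAngles,
                      ifelse(object@mtPulse, "+MT", "")), collapse = ", "),
        "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "SignalStack", function(object) {
  d <- dim(object@signal)
  cat("SignalStack: ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4L], " volumes (", object@acquisition@modality, ")\n", sep = "")
  show(object@acquisition)
})

setMethod("show", "ParameterMaps", function(object) {
  if (!length(object@maps)) {
    cat("ParameterMaps: empty\n")
    return(invisible(NULL))
  }
  d <- dim(object@maps[[1L]])
  cat("ParameterMaps: ", paste(d, collapse = " x "), " voxels; maps: ",
      paste(names(object@maps), collapse = ", "), "\n", sep = "")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth phantom\n")
  show(object@maps)
  cat("  ROI voxels: ", sum(object@roi), " of ", length(object@roi),
      "; regions: ", length(unique(as.vector(object@regions))), "\n", sep = "")
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec '", object@name, "': ",
      paste(object@parameterNames, collapse = ", "), "\n", sep = "")
  for (i in seq_along(object@parameterNames))
    cat(sprintf("  %-8s in [%g, %g]\n", object@parameterNames[i],
                object@lower[i], object@upper[i]))
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult (", if (object@converged) "converged" else "not converged",
      ", ", object@nIter, " iterations)\n", sep = "")
  print(signif(rbind(estimate = object@estimate, spread = object@spread), 6))
  cat("  rss: ", signif(object@rss, 6), "\n", sep = "")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec: ", paste(object@gridShape, collapse = " x "),
      " grid, ", object@nRegions, " regions, noise sigma ",
      object@noiseSigma, ", seed ", object@seed, "\n", sep = "")
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec: ", object@nSections, " sections, target |r| ",
      object@collagenMtR, ", noise multiplier ", object@noiseSd,
      ", seed ", object@seed, "\n", sep = "")
})
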