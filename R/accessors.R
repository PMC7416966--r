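## Accessor generics and show methods for the S4 containers.

#' Accessors for retinacuity objects
#'
#' Small accessor generics exposing the slots of the package's S4 classes:
#' `frames`, `checkSizeUm`, `frameRateHz`, `nFrames`, `spikeTimes`,
#' `durationS`, `staKernel`, `nSpikes`, `diameterUm`, `diameterSeUm`,
#' `rfCenterUm`, `rfVisible`, `nonlinearity`, `temporalKernel`,
#' `spatialSigmaUm`, `cellCenters`, `spacingUm`, `nCells`, `rateArray`,
#' `positionSet`, `deltaTS`, `acuityUm`, `snellen`, `successMatrix`,
#' `nTrials`.
#'
#' @param x an object of the class the accessor applies to.
#' @param cell optional cell name/index for `spikeTimes`.
#' @return the slot value (see the class documentation for units).
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "CheckerboardStimulus", function(x) x@frames)

#' @rdname accessors
#' @export
setGeneric("checkSizeUm", function(x) standardGeneric("checkSizeUm"))
#' @rdname accessors
#' @export
setMethod("checkSizeUm", "CheckerboardStimulus", function(x) x@checkSizeUm)
#' @rdname accessors
#' @export
setMethod("checkSizeUm", "STA", function(x) x@checkSizeUm)

#' @rdname accessors
#' @export
setGeneric("frameRateHz", function(x) standardGeneric("frameRateHz"))
#' @rdname accessors
#' @export
setMethod("frameRateHz", "CheckerboardStimulus", function(x) x@frameRateHz)
#' @rdname accessors
#' @export
setMethod("frameRateHz", "STA", function(x) x@frameRateHz)
#' @rdname accessors
#' @export
setMethod("frameRateHz", "LNModel", function(x) x@frameRateHz)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "CheckerboardStimulus", function(x) dim(x@frames)[3L])

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x, cell) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setMethod("spikeTimes", "SpikeTrains", function(x, cell) {
  if (missing(cell)) x@spikes else x@spikes[[cell]]
})

#' @rdname accessors
#' @export
setGeneric("durationS", function(x) standardGeneric("durationS"))
#' @rdname accessors
#' @export
setMethod("durationS", "SpikeTrains", function(x) x@durationS)

#' @rdname accessors
#' @export
setGeneric("staKernel", function(x) standardGeneric("staKernel"))
#' @rdname accessors
#' @export
setMethod("staKernel", "STA", function(x) x@kernel)

#' @rdname accessors
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))
#' @rdname accessors
#' @export
setMethod("nSpikes", "STA", function(x) x@nSpikes)

#' @rdname accessors
#' @export
setGeneric("diameterUm", function(x) standardGeneric("diameterUm"))
#' @rdname accessors
#' @export
setMethod("diameterUm", "GaussianRFFit", function(x) x@diameterUm)

#' @rdname accessors
#' @export
setGeneric("diameterSeUm", function(x) standardGeneric("diameterSeUm"))
#' @rdname accessors
#' @export
setMethod("diameterSeUm", "GaussianRFFit", function(x) x@diameterSeUm)

#' @rdname accessors
#' @export
setGeneric("rfCenterUm", function(x) standardGeneric("rfCenterUm"))
#' @rdname accessors
#' @export
setMethod("rfCenterUm", "GaussianRFFit", function(x) x@centerUm)

#' @rdname accessors
#' @export
setGeneric("rfVisible", function(x) standardGeneric("rfVisible"))
#' @rdname accessors
#' @export
setMethod("rfVisible", "GaussianRFFit", function(x) x@rfVisible)

#' @rdname accessors
#' @export
setGeneric("nonlinearity", function(x) standardGeneric("nonlinearity"))
#' @rdname accessors
#' @export
setMethod("nonlinearity", "LNModel", function(x) x@nonlinearity)

#' @rdname accessors
#' @export
setGeneric("temporalKernel", function(x) standardGeneric("temporalKernel"))
#' @rdname accessors
#' @export
setMethod("temporalKernel", "LNModel", function(x) x@temporalKernel)
#' @rdname accessors
#' @export
setMethod("temporalKernel", "GroundTruthCell", function(x) x@temporalKernel)

#' @rdname accessors
#' @export
setGeneric("spatialSigmaUm", function(x) standardGeneric("spatialSigmaUm"))
#' @rdname accessors
#' @export
setMethod("spatialSigmaUm", "LNModel", function(x) x@spatialSigmaUm)

#' @rdname accessors
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))
#' @rdname accessors
#' @export
setMethod("cellCenters", "PopulationGrid", function(x) x@cellCentersUm)

#' @rdname accessors
#' @export
setGeneric("spacingUm", function(x) standardGeneric("spacingUm"))
#' @rdname accessors
#' @export
setMethod("spacingUm", "PopulationGrid", function(x) x@spacingUm)

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setMethod("nCells", "PopulationGrid", function(x) nrow(x@cellCentersUm))
#' @rdname accessors
#' @export
setMethod("nCells", "RateTable", function(x) dim(x@f)[1L])

#' @rdname accessors
#' @export
setGeneric("rateArray", function(x) standardGeneric("rateArray"))
#' @rdname accessors
#' @export
setMethod("rateArray", "RateTable", function(x) x@f)

#' @rdname accessors
#' @export
setGeneric("positionSet", function(x) standardGeneric("positionSet"))
#' @rdname accessors
#' @export
setMethod("positionSet", "RateTable", function(x) x@positionsUm)

#' @rdname accessors
#' @export
setGeneric("deltaTS", function(x) standardGeneric("deltaTS"))
#' @rdname accessors
#' @export
setMethod("deltaTS", "RateTable", function(x) x@deltaTS)

#' @rdname accessors
#' @export
setGeneric("acuityUm", function(x) standardGeneric("acuityUm"))
#' @rdname accessors
#' @export
setMethod("acuityUm", "AcuityResult", function(x) x@acuityUm)

#' @rdname accessors
#' @export
setGeneric("snellen", function(x) standardGeneric("snellen"))
#' @rdname accessors
#' @export
setMethod("snellen", "AcuityResult", function(x) x@snellen)

#' @rdname accessors
#' @export
setGeneric("successMatrix", function(x) standardGeneric("successMatrix"))
#' @rdname accessors
#' @export
setMethod("successMatrix", "AcuityResult", function(x) x@success)

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setMethod("nTrials", "AcuityResult", function(x) x@nTrials)

setMethod("show", "CheckerboardStimulus", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "CheckerboardStimulus: %d x %d checks, %d frames @ %g Hz, check %g um (seed %d)\n",
    d[1], d[2], d[3], object@frameRateHz, object@checkSizeUm, object@seed))
})

setMethod("show", "SpikeTrains", function(object) {
  n <- vapply(object@spikes, length, integer(1))
  cat(sprintf("SpikeTrains: %d cells, %.1f s, %d spikes total\n",
              length(n), object@durationS, sum(n)))
})

setMethod("show", "STA", function(object) {
  d <- dim(object@kernel)
  cat(sprintf("STA: %d x %d checks x %d lags (%g ms @ %g Hz), %d spikes\n",
              d[1], d[2], d[3], object@windowMs, object@frameRateHz,
              object@nSpikes))
})

setMethod("show", "GaussianRFFit", function(object) {
  cat(sprintf(paste0(
    "GaussianRFFit: center (%.1f, %.1f) um, diameter %.1f um",
    " (SE %s), converged=%s, visible=%s\n"),
    object@centerUm[1], object@centerUm[2], object@diameterUm,
    ifelse(is.na(object@diameterSeUm), "not estimated",
           sprintf("%.1f um", object@diameterSeUm)),
    object@converged, object@rfVisible))
})

setMethod("show", "Softplus", function(object) {
  cat(sprintf("Softplus: alpha=%.4g Hz, beta=%.4g, theta=%.4g\n",
              object@alpha, object@beta, object@theta))
})

setMethod("show", "LNModel", function(object) {
  cat(sprintf("LNModel (%s coding): %d-lag kernel @ %g Hz, sigma %s um\n",
              object@inputCoding, length(object@temporalKernel),
              object@frameRateHz,
              ifelse(is.na(object@spatialSigmaUm), "-",
                     sprintf("%.1f", object@spatialSigmaUm))))
  show(object@nonlinearity)
})

setMethod("show", "PopulationGrid", function(object) {
  cat(sprintf(paste0(
    "PopulationGrid: %d cells on %.2f um lattice, extent %g x %g um\n",
    "  density %g /mm^2, transfection ratio %g\n"),
    nrow(object@cellCentersUm), object@spacingUm,
    object@extentUm[1], object@extentUm[2],
    object@densityMm2, object@transfectionRatio))
})

setMethod("show", "RateTable", function(object) {
  d <- dim(object@f)
  cat(sprintf(
    "RateTable: %d cells x %d positions x %d letters, size %g um, dt %g s\n",
    d[1], d[2], d[3], object@sizeUm, object@deltaTS))
})

setMethod("show", "AcuityResult", function(object) {
  cat(sprintf("AcuityResult: %d sizes x %d time steps, %d trials/size\n",
              nrow(object@success), ncol(object@success), object@nTrials))
  if (is.na(object@acuityUm)) {
    cat("  acuity: worse than largest tested letter\n")
  } else {
    cat(sprintf("  acuity: %g um (Snellen %s)\n",
                object@acuityUm, object@snellen))
  }
})
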