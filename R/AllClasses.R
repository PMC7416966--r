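#' @import methods
NULL

#' Binary white-noise checkerboard stimulus
#'
#' A flickering black-and-white checkerboard in which the intensity of each
#' check is redrawn independently from a Bernoulli(0.5) distribution at every
#' frame. This is the probe stimulus for spike-triggered receptive-field
#' estimation and for fitting linear-nonlinear encoding models.
#'
#' @slot frames numeric array, height x width x frames, values in \{0, 1\}.
#' @slot checkSizeUm physical side length of one check, micrometers.
#' @slot frameRateHz stimulus update rate, Hz.
#' @slot seed integer seed the frames were generated from.
#'
#' @seealso [generateCheckerboard()]
#' @exportClass CheckerboardStimulus
setClass("CheckerboardStimulus",
  representation(frames = "array", checkSizeUm = "numeric",
                 frameRateHz = "numeric", seed = "integer"))

setValidity("CheckerboardStimulus", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3-d array (H x W x T)")
  if (any(d < 1L)) return("all stimulus dimensions must be >= 1")
  if (length(object@checkSizeUm) != 1L || object@checkSizeUm <= 0)
    return("checkSizeUm must be a single positive number")
  if (length(object@frameRateHz) != 1L || object@frameRateHz <= 0)
    return("frameRateHz must be a single positive number")
  if (!all(object@frames == 0 | object@frames == 1))
    return("frames must contain only 0 and 1")
  TRUE
})

#' Ground-truth linear-nonlinear Poisson model cell
#'
#' The generating parameters of one synthetic ganglion cell: an isotropic
#' Gaussian spatial receptive field, a temporal kernel sampled at the frame
#' rate, and a softplus output nonlinearity
#' \eqn{r = \alpha \log(1 + e^{\beta(x + \theta)})}.
#'
#' @slot centerUm receptive-field center, micrometers (x, y).
#' @slot sigmaUm Gaussian SD of the spatial receptive field, micrometers.
#' @slot temporalKernel numeric vector of frame-lag weights, element 1 being
#'   the lag nearest the spike.
#' @slot alpha,beta,theta softplus parameters (alpha in Hz).
#'
#' @seealso [groundTruthCell()], [lnRate()]
#' @exportClass GroundTruthCell
setClass("GroundTruthCell",
  representation(centerUm = "numeric", sigmaUm = "numeric",
                 temporalKernel = "numeric",
                 alpha = "numeric", beta = "numeric", theta = "numeric"))

setValidity("GroundTruthCell", function(object) {
  if (length(object@centerUm) != 2L) return("centerUm must have length 2")
  if (object@sigmaUm <= 0) return("sigmaUm must be positive")
  if (length(object@temporalKernel) < 1L) return("temporal kernel is empty")
  if (object@alpha < 0) return("alpha must be >= 0")
  TRUE
})

#' Spike trains for a set of cells
#'
#' Per-cell sorted spike times over a single stimulus run. Spike times are in
#' seconds from stimulus onset; frame bins are half-open \[k/f, (k+1)/f).
#'
#' @slot spikes named list, one sorted numeric vector of spike times per cell.
#' @slot durationS recording duration, seconds.
#'
#' @exportClass SpikeTrains
setClass("SpikeTrains",
  representation(spikes = "list", durationS = "numeric"))

setValidity("SpikeTrains", function(object) {
  if (object@durationS <= 0) return("durationS must be positive")
  for (s in object@spikes) {
    if (length(s) && (is.unsorted(s) || any(s < 0) || any(s >= object@durationS)))
      return("spike times must be sorted and lie in [0, durationS)")
  }
  TRUE
})

#' Spike-triggered average
#'
#' The average (mean-centered) stimulus in a time window preceding each
#' spike: a 3-d description of the receptive field, two dimensions of space
#' and one of time.
#'
#' @slot kernel array height x width x lags; lag 1 is the frame nearest the
#'   spike, lag L the earliest.
#' @slot windowMs averaging window, milliseconds.
#' @slot frameRateHz stimulus frame rate, Hz.
#' @slot checkSizeUm check size of the probe stimulus, micrometers.
#' @slot nSpikes number of spikes entering the average.
#'
#' @seealso [computeSTA()]
#' @exportClass STA
setClass("STA",
  representation(kernel = "array", windowMs = "numeric",
                 frameRateHz = "numeric", checkSizeUm = "numeric",
                 nSpikes = "integer"))

setValidity("STA", function(object) {
  d <- dim(object@kernel)
  if (length(d) != 3L) return("kernel must be H x W x L")
  L <- round(object@windowMs * object@frameRateHz / 1000)
  if (d[3L] != L)
    return(sprintf("lag count %d != round(window * rate) = %d", d[3L], L))
  if (object@nSpikes < 1L) return("nSpikes must be >= 1")
  TRUE
})

#' Two-dimensional Gaussian receptive-field fit
#'
#' Least-squares fit of an elliptical Gaussian (plus baseline) to a spatial
#' receptive-field map. The receptive-field diameter is defined as
#' \eqn{2\sqrt{\sigma_x \sigma_y}}, the diameter of the circle with the same
#' area as the 1-SD ellipse.
#'
#' @slot centerUm fitted center (x, y), micrometers.
#' @slot sigmaXUm,sigmaYUm Gaussian SDs along the principal axes, micrometers.
#' @slot phiRad orientation of the first principal axis, radians.
#' @slot amplitude,baseline fitted amplitude and offset, stimulus units.
#' @slot diameterUm \eqn{2\sqrt{\sigma_x\sigma_y}}, micrometers.
#' @slot diameterSeUm bootstrap standard error of the diameter (NA until
#'   [bootstrapRFError()] is run).
#' @slot fitResidual root-mean-square fit residual, stimulus units.
#' @slot converged did the optimizer converge with sigmas off the bounds?
#' @slot rfVisible is the fitted amplitude distinguishable from the noise
#'   floor (a visible receptive field)?
#'
#' @seealso [fitGaussianRF()], [bootstrapRFError()]
#' @exportClass GaussianRFFit
setClass("GaussianRFFit",
  representation(centerUm = "numeric", sigmaXUm = "numeric",
                 sigmaYUm = "numeric", phiRad = "numeric",
                 amplitude = "numeric", baseline = "numeric",
                 diameterUm = "numeric", diameterSeUm = "numeric",
                 fitResidual = "numeric", converged = "logical",
                 rfVisible = "logical"))

setValidity("GaussianRFFit", function(object) {
  if (object@converged) {
    if (object@sigmaXUm <= 0 || object@sigmaYUm <= 0)
      return("sigmas must be positive")
    dd <- 2 * sqrt(object@sigmaXUm * object@sigmaYUm)
    if (abs(object@diameterUm - dd) > 1e-6 * max(1, dd))
      return("diameterUm must equal 2*sqrt(sigmaX*sigmaY)")
  }
  if (!is.na(object@diameterSeUm) && object@diameterSeUm < 0)
    return("diameterSeUm must be >= 0")
  TRUE
})

#' Softplus nonlinearity
#'
#' The parametrized rectifying nonlinearity
#' \eqn{r(x) = \alpha \log(1 + e^{\beta (x + \theta)})} mapping the filtered
#' stimulus (generator signal) to a firing rate in Hz.
#'
#' @slot alpha rate scale, Hz (must be >= 0).
#' @slot beta gain, inverse stimulus units.
#' @slot theta offset, stimulus units.
#'
#' @seealso [softplusEval()], [fitSoftplusMLE()]
#' @exportClass Softplus
setClass("Softplus",
  representation(alpha = "numeric", beta = "numeric", theta = "numeric"))

setValidity("Softplus", function(object) {
  if (object@alpha < 0) return("alpha must be >= 0")
  TRUE
})

#' Fitted softplus with optimizer diagnostics
#'
#' @slot logLik maximized Poisson log-likelihood (up to the count-factorial
#'   constant).
#' @slot gradNorm max absolute component of the scaled gradient at the
#'   returned optimum.
#' @slot converged optimizer convergence flag.
#' @exportClass SoftplusFit
setClass("SoftplusFit", contains = "Softplus",
  representation(logLik = "numeric", gradNorm = "numeric",
                 converged = "logical"))

#' Linear-nonlinear encoding model
#'
#' A separable linear filter (spatial map times temporal kernel) followed by
#' a softplus nonlinearity. `inputCoding` records whether the generator
#' signal is computed from raw \{0,1\} luminance ("raw01") or mean-centered
#' \{-0.5, +0.5\} frames ("centered"); models fitted from spike-triggered
#' averages use centered coding.
#'
#' @slot spatialFilter spatial weight map (may be 0 x 0 when the model is
#'   specified by `spatialSigmaUm` alone, as in the population model).
#' @slot temporalKernel frame-lag weights, element 1 nearest the spike.
#' @slot nonlinearity a [Softplus-class] object.
#' @slot frameRateHz frame rate the temporal kernel is sampled at, Hz.
#' @slot checkSizeUm micrometers per spatial-filter pixel.
#' @slot spatialSigmaUm SD of the equivalent isotropic Gaussian receptive
#'   field, micrometers (NA if not applicable).
#' @slot inputCoding "raw01" or "centered".
#'
#' @seealso [lnModelFromConfig()], [averageCellModel()], [predictFiringRate()]
#' @exportClass LNModel
setClass("LNModel",
  representation(spatialFilter = "matrix", temporalKernel = "numeric",
                 nonlinearity = "Softplus", frameRateHz = "numeric",
                 checkSizeUm = "numeric", spatialSigmaUm = "numeric",
                 inputCoding = "character"))

setValidity("LNModel", function(object) {
  if (!object@inputCoding %in% c("raw01", "centered"))
    return("inputCoding must be 'raw01' or 'centered'")
  if (any(!is.finite(object@temporalKernel)))
    return("temporal kernel must be finite")
  if (length(object@spatialFilter) && any(!is.finite(object@spatialFilter)))
    return("spatial filter must be finite")
  TRUE
})

#' Simulated population of reactivated ganglion cells
#'
#' Identical LN model cells placed on a square lattice whose spacing matches
#' the areal density of transfected cells:
#' spacing = 1000 / sqrt(density * transfection ratio) micrometers.
#'
#' @slot cellCentersUm N x 2 matrix of cell positions, micrometers.
#' @slot spacingUm lattice spacing, micrometers.
#' @slot extentUm simulated patch of retina (width, height), micrometers.
#' @slot model the shared [LNModel-class].
#' @slot densityMm2 ganglion-cell density, cells per mm^2.
#' @slot transfectionRatio fraction of cells expressing the protein, (0, 1].
#'
#' @seealso [buildPopulation()]
#' @exportClass PopulationGrid
setClass("PopulationGrid",
  representation(cellCentersUm = "matrix", spacingUm = "numeric",
                 extentUm = "numeric", model = "LNModel",
                 densityMm2 = "numeric", transfectionRatio = "numeric"))

setValidity("PopulationGrid", function(object) {
  if (object@transfectionRatio <= 0 || object@transfectionRatio > 1)
    return("transfectionRatio must be in (0, 1]")
  expect <- 1000 / sqrt(object@densityMm2 * object@transfectionRatio)
  if (abs(object@spacingUm - expect) > 1e-9 * expect)
    return("spacingUm must equal 1000/sqrt(density * ratio)")
  cc <- object@cellCentersUm
  if (ncol(cc) != 2L) return("cellCentersUm must be N x 2")
  if (any(cc[, 1] < 0 | cc[, 1] > object@extentUm[1] |
          cc[, 2] < 0 | cc[, 2] > object@extentUm[2]))
    return("all cell centers must lie inside the extent")
  TRUE
})

#' Firing-rate table f(cell, position, letter)
#'
#' Deterministic firing rate of every cell in response to every candidate
#' letter position and orientation, for one letter size. This is the
#' quantity the ideal-observer decoder assumes perfect knowledge of.
#'
#' @slot f rate array, cells x positions x letters, Hz.
#' @slot positionsUm P x 2 matrix of candidate letter-center positions.
#' @slot letters the four orientations ("right", "up", "left", "down").
#' @slot sizeUm letter height, micrometers.
#' @slot deltaTS presentation duration per position, seconds.
#' @slot pixelSizeUm rendering pixel, micrometers.
#' @slot canvasCenterUm center of the rendering canvas, micrometers.
#'
#' @seealso [computeRateTable()]
#' @exportClass RateTable
setClass("RateTable",
  representation(f = "array", positionsUm = "matrix", letters = "character",
                 sizeUm = "numeric", deltaTS = "numeric",
                 pixelSizeUm = "numeric", canvasCenterUm = "numeric"))

setValidity("RateTable", function(object) {
  d <- dim(object@f)
  if (length(d) != 3L) return("f must be cells x positions x letters")
  if (d[2L] != nrow(object@positionsUm)) return("position count mismatch")
  if (d[3L] != length(object@letters)) return("letter count mismatch")
  if (any(object@f < 0)) return("rates must be >= 0")
  if (nrow(object@positionsUm) < 1L) return("need at least one position")
  TRUE
})

#' Result of an in silico acuity test
#'
#' Success-rate curves over exposure time and letter size, plus the acuity
#' read off at 1 s with the strict "> 80 percent correct" rule and its
#' Snellen conversion (25 um letter == 20/20, linear scaling).
#'
#' @slot success matrix of success fractions, letter sizes x time steps.
#' @slot sizesUm tested letter sizes (ascending), micrometers.
#' @slot timesS decoding times (end of each presentation), seconds.
#' @slot acuityUm smallest tested size with success > 0.8 at the final time
#'   (NA if no tested size qualifies: worse than the largest tested letter).
#' @slot snellen Snellen string for the acuity (NA if unresolved).
#' @slot nTrials trials per size.
#' @slot sdOverRepeats SD of acuity over outer repetitions (NA if one run).
#' @slot seed master seed of the run.
#'
#' @seealso [runAcuityTest()], [estimateAcuity()]
#' @exportClass AcuityResult
setClass("AcuityResult",
  representation(success = "matrix", sizesUm = "numeric", timesS = "numeric",
                 acuityUm = "numeric", snellen = "character",
                 nTrials = "integer", sdOverRepeats = "numeric",
                 seed = "integer"))

setValidity("AcuityResult", function(object) {
  if (any(object@success < 0 | object@success > 1))
    return("success fractions must lie in [0, 1]")
  if (nrow(object@success) != length(object@sizesUm))
    return("one success row per letter size required")
  TRUE
})
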