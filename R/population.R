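## Full reactivated-retina population: square grid of identical LN cells
## and their deterministic rate table over letter positions/orientations.

#' Build the simulated population of reactivated ganglion cells
#'
#' Cells are placed on a square lattice with spacing
#' `1000 / sqrt(densityMm2 * transfectionRatio)` micrometers, matching the
#' areal density of transfected cells; non-transfected cells transmit no
#' stimulus information and are omitted entirely. The defaults correspond
#' to the macaque fovea (51108 cells/mm^2) with a 40 percent transfection
#' ratio, i.e. a spacing of about 7 um. Optional uniform positional jitter
#' makes the grid irregular; the decoding results are insensitive to it.
#'
#' @param densityMm2 ganglion-cell density, cells per mm^2.
#' @param transfectionRatio fraction of transfected cells, (0, 1].
#' @param extentUm simulated patch (width, height), micrometers; must cover
#'   the letter plus the jitter window plus a receptive-field margin (see
#'   [requiredExtentUm()]).
#' @param model the shared [LNModel-class] (needs a finite
#'   `spatialSigmaUm`).
#' @param jitterSdUm SD of optional Gaussian positional jitter (default 0 =
#'   regular grid).
#' @param seed RNG seed, used only when `jitterSdUm > 0`.
#' @return A [PopulationGrid-class] object.
#' @export
buildPopulation <- function(densityMm2 = 51108, transfectionRatio = 0.4,
                            extentUm = c(700, 700), model = lnModelFromConfig(),
                            jitterSdUm = 0, seed = NULL) {
  stopIfNot(densityMm2 > 0, "density must be positive")
  stopIfNot(transfectionRatio > 0 && transfectionRatio <= 1,
            "transfectionRatio must be in (0, 1]")
  stopIfNot(is.finite(model@spatialSigmaUm),
            "population model needs a spatialSigmaUm")
  stopIfNot(all(extentUm > 0), "extent must be positive")
  spacing <- 1000 / sqrt(densityMm2 * transfectionRatio)
  stopIfNot(all(extentUm >= spacing), "extent smaller than one cell spacing")
  xs <- seq(spacing / 2, extentUm[1], by = spacing)
  ys <- seq(spacing / 2, extentUm[2], by = spacing)
  centers <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  if (jitterSdUm > 0) {
    centers <- withSeed(seed, {
      jit <- matrix(rnorm(length(centers), 0, jitterSdUm), ncol = 2)
      centers + jit
    })
    centers[, 1] <- pmin(pmax(centers[, 1], 0), extentUm[1])
    centers[, 2] <- pmin(pmax(centers[, 2], 0), extentUm[2])
  }
  colnames(centers) <- c("x", "y")
  new("PopulationGrid", cellCentersUm = centers, spacingUm = spacing,
      extentUm = extentUm, model = model, densityMm2 = densityMm2,
      transfectionRatio = transfectionRatio)
}

#' Minimum extent needed for an acuity simulation
#'
#' Letter plus jitter window plus two receptive-field sigmas on each side.
#' @param maxSizeUm largest letter size tested, micrometers.
#' @param jitterWindowUm side of the square jitter window, micrometers.
#' @param sigmaUm receptive-field SD, micrometers.
#' @return required square extent side, micrometers.
#' @export
requiredExtentUm <- function(maxSizeUm, jitterWindowUm, sigmaUm) {
  maxSizeUm + jitterWindowUm + 4 * sigmaUm
}

#' Candidate letter positions for the jitter window
#'
#' A square lattice of letter-center positions covering a window centered
#' in the canvas, with one lattice step per rendering pixel. These are the
#' positions the fixational-jitter process draws from and the positions the
#' decoder sums over.
#'
#' @param canvasUm canvas extent (width, height), micrometers.
#' @param jitterWindowUm window side, micrometers (default 100).
#' @param stepUm lattice step, micrometers (default 10, the rendering
#'   pixel).
#' @return P x 2 matrix of absolute positions, micrometers.
#' @export
makePositionSet <- function(canvasUm, jitterWindowUm = 100, stepUm = 10) {
  half <- jitterWindowUm / 2
  offs <- seq(-half, half, by = stepUm)
  ctr <- canvasUm / 2
  cbind(x = rep(ctr[1] + offs, times = length(offs)),
        y = rep(ctr[2] + offs, each = length(offs)))
}

#' Deterministic rate table f(cell, position, letter)
#'
#' For every cell, candidate position and letter orientation, the firing
#' rate of the cell's LN model in response to that letter: the rendered
#' image is weighted by the cell's unit-sum Gaussian receptive field and
#' the result, scaled by the DC gain of the temporal kernel, drives the
#' softplus. Each presentation window is a single rate bin, so the table is
#' time-independent; it is also fully deterministic.
#'
#' Implementation: each letter is rendered once at the canvas center, the
#' Gaussian-weighted coverage surface is computed by separable convolution,
#' and each (cell, position) rate is read off by bilinear interpolation at
#' the cell center displaced by the letter offset.
#'
#' @param grid a [PopulationGrid-class].
#' @param sizeUm letter size, micrometers.
#' @param positionsUm P x 2 matrix of candidate letter centers (default:
#'   [makePositionSet()] over a 100 um window).
#' @param deltaTS presentation duration per position, seconds (default
#'   0.06).
#' @param pixelSizeUm rendering pixel, micrometers (default 10).
#' @return A [RateTable-class] object.
#' @export
computeRateTable <- function(grid, sizeUm, positionsUm = NULL,
                             deltaTS = 0.06, pixelSizeUm = 10) {
  model <- grid@model
  sig <- model@spatialSigmaUm
  ext <- grid@extentUm
  if (is.null(positionsUm))
    positionsUm <- makePositionSet(ext, 100, pixelSizeUm)
  jitterSpan <- max(apply(positionsUm, 2, function(v) diff(range(v))))
  if (min(ext) < sizeUm + jitterSpan + 4 * sig)
    stop("extent too small for letter + jitter window + RF margin",
         call. = FALSE)
  ctr <- ext / 2
  ## Gaussian receptive-field kernel sampled at pixel resolution, unit sum
  K <- ceiling(4 * sig / pixelSizeUm)
  g <- exp(-((-K:K) * pixelSizeUm)^2 / (2 * sig^2))
  g <- g / sum(g)
  gain <- sum(model@temporalKernel)
  nl <- model@nonlinearity
  centers <- grid@cellCentersUm
  N <- nrow(centers); P <- nrow(positionsUm)
  f <- array(0, dim = c(N, P, 4L))
  off <- if (model@inputCoding == "centered") -0.5 else 0
  x0 <- 0.5 * pixelSizeUm; y0 <- 0.5 * pixelSizeUm
  for (ell in 1:4) {
    img <- renderLetterE(sizeUm, ell, ctr, pixelSizeUm, ext)
    S <- sepConv2(img, g, g)          # coverage <w, image> at pixel centers
    for (p in seq_len(P)) {
      dxy <- positionsUm[p, ] - ctr
      cov <- bilinearInterp(S, x0, pixelSizeUm, y0, pixelSizeUm,
                            centers[, 1] - dxy[1], centers[, 2] - dxy[2])
      f[, p, ell] <- softplusEval(nl, gain * (pmin(pmax(cov, 0), 1) + off))
    }
  }
  new("RateTable", f = f, positionsUm = positionsUm,
      letters = letterOrientations(), sizeUm = sizeUm, deltaTS = deltaTS,
      pixelSizeUm = pixelSizeUm, canvasCenterUm = ctr)
}

#' Sample the fixational-jitter position sequence
#'
#' The letter jumps to a new position drawn i.i.d. uniformly from the
#' candidate set every `jitterPeriodS` seconds, mimicking fixational eye
#' movements; a 1 s exposure with the default 67 ms period gives 15
#' presentations.
#'
#' @param positionsUm P x 2 candidate position matrix.
#' @param durationS exposure duration, seconds.
#' @param jitterPeriodS time per position, seconds (<= duration).
#' @param seed RNG seed.
#' @return n x 2 matrix of positions with the drawn indices in attribute
#'   `"indices"`.
#' @export
samplePositionSequence <- function(positionsUm, durationS,
                                   jitterPeriodS = 0.067, seed = 1) {
  stopIfNot(nrow(positionsUm) >= 1, "empty position set")
  stopIfNot(jitterPeriodS <= durationS, "jitter period exceeds the duration")
  n <- ceiling(durationS / jitterPeriodS)
  idx <- withSeed(seed, sample.int(nrow(positionsUm), n, replace = TRUE))
  out <- positionsUm[idx, , drop = FALSE]
  attr(out, "indices") <- idx
  out
}

#' Simulate Poisson population spike counts for a letter presentation
#'
#' Counts are independent Poisson draws, cell by cell and presentation by
#' presentation, with mean f(cell, position, letter) * deltaT.
#'
#' @param table a [RateTable-class].
#' @param trueLetter orientation index 1..4 (or name).
#' @param positionIdx vector of position indices into the table's position
#'   set, one per presentation.
#' @param seed RNG seed.
#' @return integer matrix, presentations x cells.
#' @export
simulatePopulationResponse <- function(table, trueLetter, positionIdx, seed) {
  if (is.character(trueLetter)) trueLetter <- match(trueLetter, table@letters)
  P <- nrow(table@positionsUm)
  stopIfNot(all(positionIdx >= 1 & positionIdx <= P),
            "position outside the candidate set")
  lam <- t(table@f[, positionIdx, trueLetter, drop = FALSE][, , 1]) *
    table@deltaTS
  withSeed(seed, {
    matrix(rpois(length(lam), lam), nrow = length(positionIdx))
  })
}
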