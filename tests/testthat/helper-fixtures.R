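## Shared fixtures: everything is generated in code at test time.

.fixtureCache <- new.env(parent = emptyenv())

## A ground-truth LNP cell probed with a binary checkerboard, plus its
## rate trace and a Poisson spike train. Cached per parameter set.
lnpRecording <- function(seed = 101, nFrames = 24000, frameRateHz = 40,
                         heightChecks = 12, widthChecks = 12,
                         checkSizeUm = 50, sigmaUm = 41,
                         centerUm = c(300, 300)) {
  key <- paste(seed, nFrames, frameRateHz, heightChecks, widthChecks,
               checkSizeUm, sigmaUm, paste(centerUm, collapse = "_"),
               sep = "|")
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  stim <- generateCheckerboard(heightChecks, widthChecks, nFrames,
                               frameRateHz, checkSizeUm, seed = seed)
  cell <- groundTruthCell(centerUm = centerUm, sigmaUm = sigmaUm,
                          frameRateHz = frameRateHz)
  rate <- lnRate(cell, stim)
  spikes <- simulatePoissonSpikes(rate, frameRateHz, seed = seed + 1)
  out <- list(stim = stim, cell = cell, rate = rate, spikes = spikes)
  .fixtureCache[[key]] <- out
  out
}

## Small hand-built rate table for decoder tests.
toyRateTable <- function(f, deltaTS = 0.06) {
  P <- dim(f)[2L]
  new("RateTable", f = f,
      positionsUm = cbind(seq_len(P) * 10, rep(0, P)),
      letters = letterOrientations(), sizeUm = 50, deltaTS = deltaTS,
      pixelSizeUm = 10, canvasCenterUm = c(50, 50))
}

## A small population grid for end-to-end decoding tests: spacing 10 um
## (density * ratio = 1e4 cells/mm^2) so cells are pixel-aligned.
smallGrid <- function(rfDiameterUm = 82, extent = 400, alpha = NULL) {
  model <- lnModelFromConfig(rfDiameterUm, 30)
  if (!is.null(alpha)) {
    nl <- nonlinearity(model)
    model <- lnModel(model@spatialFilter, temporalKernel(model),
                     softplus(alpha, nl@beta, nl@theta), 30,
                     spatialSigmaUm = model@spatialSigmaUm,
                     inputCoding = "raw01")
  }
  buildPopulation(densityMm2 = 1e4, transfectionRatio = 1,
                  extentUm = c(extent, extent), model = model)
}

## Unit-square count of the 5x5 tumbling-E mask, the independent oracle
## for the rendered ink fraction: spine column plus three full bars.
eMaskInkSquares <- function() {
  mask <- matrix(0L, 5, 5)
  mask[, 1] <- 1L          # spine (left column)
  mask[c(1, 3, 5), ] <- 1L # bottom, middle, top bars
  sum(mask)
}
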