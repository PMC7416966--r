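test_that("softplus evaluation matches its closed forms", {
  p <- softplus(alpha = 7, beta = 3, theta = -0.2)
  expect_equal(softplusEval(p, 0.2), 7 * log(2))        # x = -theta
  expect_equal(softplusEval(softplus(0, 3, 1), c(-5, 0, 5)), c(0, 0, 0))
  ## deep linear asymptote: beta*(x+theta) = 50
  x <- 50 / 3 + 0.2
  expect_equal(softplusEval(p, x), 7 * 50, tolerance = 1e-15)
  ## monotone and non-negative
  xs <- seq(-2, 2, by = 0.1)
  r <- softplusEval(p, xs)
  expect_true(all(r >= 0))
  expect_true(all(diff(r) > 0))
})

test_that("stimulus filtering matches a brute-force triple loop", {
  stim <- generateCheckerboard(4, 4, 10, 40, 50, seed = 3)
  set.seed(4)
  W <- matrix(runif(16), 4)
  k <- c(0.5, 0.3, -0.2)
  mod <- lnModel(W, k, softplus(1, 1, 0), 40, 50, inputCoding = "centered")
  x <- filterStimulus(mod, stim)
  expect_equal(attr(x, "warmup"), 2)
  expect_true(all(is.na(x[1:2])))
  s <- frames(stim) - 0.5
  for (t in 3:10) {
    acc <- 0
    for (l in 1:3) for (i in 1:4) for (j in 1:4)
      acc <- acc + k[l] * W[i, j] * s[i, j, t - l + 1]
    expect_equal(unname(x[t]), acc, tolerance = 1e-12)
  }
  ## impulse temporal kernel reduces to a lagged spatial dot product
  modImp <- lnModel(W, c(0, 1), softplus(1, 1, 0), 40, 50,
                    inputCoding = "centered")
  xi <- filterStimulus(modImp, stim)
  dots <- apply(s, 3, function(fr) sum(W * fr))
  expect_equal(unname(xi[2:10]), dots[1:9], tolerance = 1e-12)
  ## uniform gray (centered zero) stimulus gives a zero generator
  gray <- new("CheckerboardStimulus", frames = array(1, c(4, 4, 10)),
              checkSizeUm = 50, frameRateHz = 40, seed = 0L)
  gray@frames[] <- 0
  mod0 <- lnModel(W, k, softplus(1, 1, 0), 40, 50, inputCoding = "centered")
  x0 <- filterStimulus(mod0, gray) + 0.5 * sum(W) * sum(k)  # undo centering
  expect_equal(unname(x0[3:10]), rep(0, 8), tolerance = 1e-12)
  ## dimension mismatch
  expect_error(filterStimulus(mod, generateCheckerboard(5, 4, 10, 40, 50, 1)),
               "do not match")
})

test_that("softplus MLE recovers the generating nonlinearity", {
  fx <- lnpRecording()
  cell <- fx$cell
  d <- dim(frames(fx$stim))
  w <- retinacuity:::gaussianWeightMap(cell@centerUm, cell@sigmaUm,
                                       d[1], d[2], 50)
  q <- as.numeric(crossprod(as.vector(w), matrix(frames(fx$stim), nrow = 144)))
  x <- retinacuity:::applyTemporalKernel(q, temporalKernel(cell), pad = 0.5)
  n <- binSpikeCounts(fx$spikes, d[3], 40)
  fit <- fitSoftplusMLE(x, n, 40, seed = 2)
  expect_true(fit@converged)
  expect_lt(fit@gradNorm, 1e-6)
  ## fitted rate curve vs generating curve over the observed range
  xx <- seq(quantile(x, 0.005), quantile(x, 0.995), length.out = 200)
  rTrue <- cell@alpha * log1p(exp(cell@beta * (xx + cell@theta)))
  rFit <- softplusEval(fit, xx)
  expect_lt(sqrt(mean((rFit - rTrue)^2)) / sqrt(mean(rTrue^2)), 0.1)
  ## Poisson MLE moment property: predicted mean rate ~ empirical mean rate
  expect_equal(mean(softplusEval(fit, x)), mean(n) * 40, tolerance = 0.02)
})

test_that("softplus MLE handles degenerate generators", {
  set.seed(5)
  n <- rpois(2000, 0.3)
  fit <- fitSoftplusMLE(rep(1.7, 2000), n, 40, seed = 3)
  expect_equal(softplusEval(fit, 1.7), mean(n) * 40, tolerance = 0.01)
  expect_error(fitSoftplusMLE(rnorm(100), rep(0L, 100), 40), "all spike counts")
})

test_that("prediction scoring is affine-invariant and ceiling-bounded", {
  psth <- c(1, 4, 2, 8, 3, 6, 1, 9, 2, 5)
  trials <- matrix(rep(psth / 40, each = 6), nrow = 6)  # PSTH*rate = psth
  expect_equal(scorePrediction(psth, trials, 40)$pearsonR, 1)
  sc <- scorePrediction(3 * psth + 2, trials, 40)       # affine transform
  expect_equal(sc$pearsonR, 1)
  ## a true-model prediction sits near the reliability-implied ceiling
  fx <- lnpRecording(nFrames = 1200)
  trialsLNP <- generateRepeatTrials(fx$cell, fx$stim, 50, seed = 21)
  scLNP <- scorePrediction(fx$rate, trialsLNP, 40)
  ceiling <- sqrt(2 * scLNP$reliabilityR / (1 + scLNP$reliabilityR))
  expect_gt(scLNP$pearsonR, 0.9 * ceiling)
})

test_that("averaging cell models is translation-invariant", {
  ## cells at check centers so integer-check recentering is exact
  fx <- lnpRecording(nFrames = 12000, centerUm = c(325, 325))
  stim <- fx$stim
  cellA <- fx$cell
  cellB <- groundTruthCell(c(225, 275), 41, 40)
  spA <- fx$spikes
  spB <- simulatePoissonSpikes(lnRate(cellB, stim), 40, seed = 61)
  staA <- computeSTA(stim, spA); staB <- computeSTA(stim, spB)
  fitA <- fitGaussianRF(extractSpatialRF(staA), 50)
  fitB <- fitGaussianRF(extractSpatialRF(staB), 50)
  ## single cell: the averaged model is that cell's re-centered model
  m1 <- averageCellModel(list(staA), list(fitA), stim, list(spA))
  expect_s4_class(m1, "LNModel")
  expect_equal(spatialSigmaUm(m1), 41, tolerance = 0.15)
  ## two same-shape cells at different positions: sigma unchanged
  m2 <- averageCellModel(list(staA, staB), list(fitA, fitB), stim,
                         list(spA, spB))
  expect_equal(spatialSigmaUm(m2), 41, tolerance = 0.15)
  ## heterogeneous diameters: averaged sigma between the members'
  ## (up to sampling error of the STAs)
  cellC <- groundTruthCell(c(275, 225), sigmaUm = 30, frameRateHz = 40)
  spC <- simulatePoissonSpikes(lnRate(cellC, stim), 40, seed = 62)
  staC <- computeSTA(stim, spC)
  fitC <- fitGaussianRF(extractSpatialRF(staC), 50)
  m3 <- averageCellModel(list(staA, staC), list(fitA, fitC), stim,
                         list(spA, spC))
  expect_gt(spatialSigmaUm(m3), 30 * 0.92)
  expect_lt(spatialSigmaUm(m3), 41 * 1.08)
  expect_error(averageCellModel(list(), list(), stim, list()), "empty")
})
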