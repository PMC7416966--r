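renderGaussianMap <- function(centerUm, sigmaUm, H, W, checkSizeUm,
                              amplitude = 1, baseline = 0) {
  xs <- (seq_len(W) - 0.5) * checkSizeUm
  ys <- (seq_len(H) - 0.5) * checkSizeUm
  baseline + amplitude * outer(exp(-(ys - centerUm[2])^2 / (2 * sigmaUm^2)),
                               exp(-(xs - centerUm[1])^2 / (2 * sigmaUm^2)))
}

test_that("a noiseless Gaussian map is recovered to within 1 percent", {
  map <- renderGaussianMap(c(310, 290), 40, 12, 12, 50)
  fit <- fitGaussianRF(map, 50)
  expect_true(fit@converged)
  expect_true(rfVisible(fit))
  expect_equal(diameterUm(fit), 80, tolerance = 0.01)
  expect_equal(rfCenterUm(fit), c(310, 290), tolerance = 0.01)
})

test_that("the Gaussian fit is translation-equivariant by one check", {
  map <- renderGaussianMap(c(300, 300), 45, 12, 12, 50)
  shifted <- retinacuity:::shiftMatrix(map, 0, 1)  # one check in x
  f0 <- fitGaussianRF(map, 50)
  f1 <- fitGaussianRF(shifted, 50)
  expect_equal(rfCenterUm(f1)[1] - rfCenterUm(f0)[1], 50, tolerance = 1e-3)
  expect_equal(rfCenterUm(f1)[2], rfCenterUm(f0)[2], tolerance = 1e-3)
  expect_equal(diameterUm(f1), diameterUm(f0), tolerance = 1e-4)
})

test_that("a pure-noise map is flagged as having no visible field", {
  set.seed(77)
  map <- matrix(rnorm(144, 0, 0.02), 12, 12)
  fit <- fitGaussianRF(map, 50)
  expect_false(rfVisible(fit))
})

test_that("bootstrap diameter error behaves like a noise-driven SD", {
  ## zero noise variance far from the center -> SE exactly 0
  map <- renderGaussianMap(c(300, 300), 40, 12, 12, 50)
  mapZero <- ifelse(map < max(map) * exp(-4.5), 0, map)  # hard-zero tails
  fit <- fitGaussianRF(mapZero, 50)
  fitB <- bootstrapRFError(fit, mapZero, 50, nBoot = 100, seed = 1)
  expect_equal(diameterSeUm(fitB), 0)

  ## doubling the injected noise SD increases the SE (across seeds)
  surface <- renderGaussianMap(c(300, 300), 40, 12, 12, 50)
  seLow <- seHigh <- numeric(6)
  for (s in 1:6) {
    set.seed(400 + s)
    m1 <- surface + matrix(rnorm(144, 0, 0.02), 12, 12)
    m2 <- surface + matrix(rnorm(144, 0, 0.04), 12, 12)
    f1 <- fitGaussianRF(m1, 50); f2 <- fitGaussianRF(m2, 50)
    seLow[s] <- diameterSeUm(bootstrapRFError(f1, m1, 50, 100, seed = s))
    seHigh[s] <- diameterSeUm(bootstrapRFError(f2, m2, 50, 100, seed = s))
  }
  expect_true(all(seHigh > seLow))

  ## SE is invariant under a sign flip of the map
  set.seed(55)
  m <- surface + matrix(rnorm(144, 0, 0.03), 12, 12)
  fPos <- fitGaussianRF(m, 50)
  fNeg <- fitGaussianRF(-m, 50)
  sePos <- diameterSeUm(bootstrapRFError(fPos, m, 50, 200, seed = 9))
  seNeg <- diameterSeUm(bootstrapRFError(fNeg, -m, 50, 200, seed = 9))
  expect_equal(sePos, seNeg, tolerance = 1e-2)

  ## SE stabilizes between 500 and 1000 replicates
  se500 <- diameterSeUm(bootstrapRFError(fPos, m, 50, 500, seed = 11))
  se1000 <- diameterSeUm(bootstrapRFError(fPos, m, 50, 1000, seed = 11))
  expect_lt(abs(se1000 - se500) / se1000, 0.1)
})

test_that("split-half reliability separates modulated from flat cells", {
  ## identical duplicated trials are perfectly reliable
  psth <- matrix(rep(c(0, 3, 1, 5, 2, 4), 200), nrow = 4, ncol = 300,
                 byrow = TRUE)
  expect_equal(splitHalfReliability(psth), 1)
  expect_error(splitHalfReliability(psth[1, , drop = FALSE]), "two repeats")

  ## homogeneous Poisson trials: reliability indistinguishable from zero
  set.seed(88)
  flat <- matrix(rpois(50 * 1200, 0.5), nrow = 50)
  expect_lt(abs(splitHalfReliability(flat)), 0.2)

  ## strongly modulated LNP cell at R = 50 passes the 0.5 selection rule
  fx <- lnpRecording(nFrames = 1200)
  tr <- generateRepeatTrials(fx$cell, fx$stim, 50, seed = 12)
  expect_gt(splitHalfReliability(tr), 0.5)

  ## constant PSTH in a half is flagged undefined
  expect_true(is.na(splitHalfReliability(matrix(0L, 4, 10))))
})

test_that("cell selection applies the strict reliability rule", {
  qc <- data.frame(cell_id = c("a", "b", "c", "d"),
                   rf_visible = c(TRUE, TRUE, FALSE, TRUE),
                   reliability_r = c(0.5, 0.51, 0.9, NA))
  expect_equal(selectCells(qc), "b")       # 0.5 exactly is rejected
  expect_length(selectCells(qc[0, ]), 0)   # empty in, empty out
  expect_equal(selectCells(qc, threshold = 0.4), c("a", "b"))
})

test_that("population diameter summary uses inverse-variance weights", {
  mkFit <- function(d, se) new("GaussianRFFit", centerUm = c(0, 0),
    sigmaXUm = d / 2, sigmaYUm = d / 2, phiRad = 0, amplitude = 1,
    baseline = 0, diameterUm = d, diameterSeUm = se, fitResidual = 0,
    converged = TRUE, rfVisible = TRUE)
  ## equal SEs reduce to the unweighted mean
  s <- populationRFSummary(list(mkFit(80, 2), mkFit(100, 2)))
  expect_equal(s$meanDiameterUm, 90)
  expect_equal(s$semUm, sd(c(80, 100)) / sqrt(2))
  ## a cell with 10x smaller SE dominates: closed-form weighted mean
  s2 <- populationRFSummary(list(mkFit(80, 0.5), mkFit(100, 5)))
  wm <- (80 / 0.25 + 100 / 25) / (1 / 0.25 + 1 / 25)
  expect_equal(s2$meanDiameterUm, wm)
  expect_lt(abs(s2$meanDiameterUm - 80), 0.5)
  ## degenerate inputs
  expect_error(populationRFSummary(list(mkFit(80, 1))), "two converged")
  expect_warning(s3 <- populationRFSummary(list(mkFit(80, 0), mkFit(100, 1))),
                 "unweighted")
  expect_equal(s3$meanDiameterUm, 90)
})
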