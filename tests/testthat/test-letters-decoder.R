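test_that("the rendered tumbling E matches the 5x5 optotype mask", {
  img <- renderLetterE(100, "right", c(100, 100), 10, c(200, 200))
  ## ink fraction from the unit-square count of the 5x5 mask
  expect_equal(sum(img) / (100 / 10)^2, eMaskInkSquares() / 25)
  expect_true(all(img %in% c(0, 1)))
  ## four 90-degree rotations are the identity
  for (o in 1:4) {
    a <- renderLetterE(100, o, c(100, 100), 10, c(200, 200))
    expect_equal(sum(a), sum(img))  # rotation preserves ink
  }
  up <- renderLetterE(100, "up", c(100, 100), 10, c(200, 200))
  ## rotating the "right" image 90 degrees CCW gives the "up" image
  expect_equal(up, t(img)[, rev(seq_len(ncol(img)))] |> unname(),
               ignore_attr = TRUE)
  ## translating by one pixel shifts the ink exactly
  shifted <- renderLetterE(100, "right", c(110, 100), 10, c(200, 200))
  expect_equal(shifted[, 2:20], img[, 1:19], ignore_attr = TRUE)
  ## degenerate sizes and off-canvas positions are rejected
  expect_error(renderLetterE(15, "right", c(100, 100), 10, c(200, 200)),
               "two pixels")
  expect_error(renderLetterE(100, "right", c(30, 100), 10, c(200, 200)),
               "does not fit")
})

test_that("eq1 letter log-likelihood matches a brute-force Poisson sum", {
  set.seed(14)
  for (rep in 1:5) {
    nc <- sample(2:3, 1); np <- sample(2:3, 1)
    f <- array(runif(nc * np * 4, 0.2, 8), dim = c(nc, np, 4))
    tb <- toyRateTable(f)
    n <- rpois(nc, 2); n <- pmin(n, 5L)
    L <- eq1LetterLoglik(n, tb)
    brute <- vapply(1:4, function(ell) {
      s <- 0
      for (p in seq_len(np)) for (i in seq_len(nc))
        s <- s + n[i] * log(f[i, p, ell]) - 0.06 * f[i, p, ell]
      s
    }, numeric(1))
    expect_equal(L, brute, tolerance = 1e-12)
  }
  ## identical tables across letters give identical scores
  fEq <- array(rep(runif(6, 1, 3), 4), dim = c(3, 2, 4))
  expect_equal(diff(range(eq1LetterLoglik(c(1L, 0L, 2L), toyRateTable(fEq)))),
               0, tolerance = 1e-12)
  ## zero counts: closed form -dt * sum(f)
  f0 <- array(runif(24, 1, 3), dim = c(3, 2, 4))
  L0 <- eq1LetterLoglik(c(0L, 0L, 0L), toyRateTable(f0))
  expect_equal(L0, -0.06 * apply(f0, 3, sum), tolerance = 1e-12)
})

test_that("the marginal decoder is a proper position mixture", {
  set.seed(15)
  f <- array(runif(2 * 3 * 4, 0.3, 6), dim = c(2, 3, 4))
  tb <- toyRateTable(f)
  n <- c(2L, 1L)
  LM <- marginalLetterLoglik(n, tb)
  brute <- vapply(1:4, function(ell) {
    log(mean(vapply(1:3, function(p)
      exp(sum(dpois(n, f[, p, ell] * 0.06, log = TRUE))), numeric(1))))
  }, numeric(1))
  expect_equal(LM, brute, tolerance = 1e-10)
  ## P = 1: marginal equals eq1 up to a letter-independent constant
  tb1 <- toyRateTable(f[, 1, , drop = FALSE])
  dEq <- eq1LetterLoglik(n, tb1) - marginalLetterLoglik(n, tb1)
  expect_equal(diff(range(dEq)), 0, tolerance = 1e-12)
  ## position-independent table reduces to the P = 1 case
  fRep <- array(0, dim = c(2, 3, 4))
  for (p in 1:3) fRep[, p, ] <- f[, 1, ]
  expect_equal(marginalLetterLoglik(n, toyRateTable(fRep)),
               marginalLetterLoglik(n, tb1), tolerance = 1e-12)
})

test_that("letter decoding takes the argmax with uniform tie-breaking", {
  expect_equal(decodeLetter(c(0, -1, -2, -3)), 1)
  set.seed(16)
  picks <- replicate(10000, decodeLetter(c(1, 1, 1, 1)))
  freq <- tabulate(picks, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 4 * sqrt(0.25 * 0.75 / 10000)))
  ## adding a constant leaves the decision unchanged
  set.seed(17)
  for (i in 1:20) {
    v <- rnorm(4)
    expect_equal(decodeLetter(v), decodeLetter(v + 123.4))
  }
})

test_that("acuity rules are applied strictly", {
  expect_equal(estimateAcuity(c(0.5, 0.7, 0.85, 0.95), c(50, 75, 100, 150)),
               100)
  expect_equal(estimateAcuity(c(0.80, 0.95), c(50, 100)), 100)  # strict >
  worse <- estimateAcuity(c(0.5, 0.6), c(50, 100))
  expect_true(is.na(worse))
  expect_equal(attr(worse, "status"), "worse than max tested")
  expect_error(estimateAcuity(c(0.9, 0.9), c(100, 50)), "ascending")
})

test_that("Snellen conversion is anchored at 25 um = 20/20", {
  expect_equal(snellenFromSize(25), "20/20")
  expect_equal(snellenFromSize(50), "20/40")
  expect_equal(snellenFromSize(250), "20/200")
  expect_error(snellenFromSize(0), "positive")
})

test_that("acuity trials are reproducible and respect chance level", {
  grid <- smallGrid(extent = 400)
  t1 <- runAcuityTrial(grid, 150, seed = 20, jitterWindowUm = 60)
  t2 <- runAcuityTrial(grid, 150, seed = 20, jitterWindowUm = 60)
  expect_identical(t1, t2)
  expect_length(t1, 15)
  ## alpha = 0 population: all rates equal, accuracy at chance (1/4)
  gridFlat <- smallGrid(extent = 400, alpha = 0)
  pos <- makePositionSet(c(400, 400), 60, 10)
  tb <- computeRateTable(gridFlat, 150, pos)
  dec <- retinacuity:::decoderPrecompute(tb, "eq1")
  hits <- vapply(1:300, function(i)
    retinacuity:::acuityTrialCore(tb, dec, 15, seed = 1000 + i)[15],
    logical(1))
  expect_lt(abs(mean(hits) - 0.25), 4 * sqrt(0.25 * 0.75 / 300))
})

test_that("the full acuity test aggregates trials deterministically", {
  grid <- smallGrid(extent = 540)
  res <- runAcuityTest(grid, c(100, 200, 300), nTrials = 40,
                       jitterWindowUm = 60, seed = 30)
  res2 <- runAcuityTest(grid, c(100, 200, 300), nTrials = 40,
                        jitterWindowUm = 60, seed = 30)
  expect_identical(successMatrix(res), successMatrix(res2))
  expect_equal(nTrials(res), 40L)
  expect_equal(dim(successMatrix(res)), c(3L, 15L))
  expect_true(all(successMatrix(res) >= 0 & successMatrix(res) <= 1))
  ## success at the largest size is at least that at the smallest
  s <- successMatrix(res)[, 15]
  expect_gte(s[3], s[1])
  ## sweep edge cases
  expect_error(sweepDensity(c(0.4, 1.5)), "\\(0, 1\\]")
  expect_equal(nrow(sweepRFSize(numeric(0))), 0)
})
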