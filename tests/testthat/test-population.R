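test_that("grid spacing follows the transfected-cell density exactly", {
  model <- lnModelFromConfig(82, 30)
  g <- buildPopulation(51108, 0.4, c(700, 700), model)
  expect_equal(spacingUm(g), 1000 / sqrt(51108 * 0.4))
  expect_equal(spacingUm(g), 6.99, tolerance = 0.001)
  expect_equal(spacingUm(g)^2 * 51108 * 0.4, 1e6)
  ## full transfection over 1 mm^2 recovers the cell density within 1%
  g1 <- buildPopulation(51108, 1, c(1000, 1000), model)
  expect_equal(nCells(g1) / 51108, 1, tolerance = 0.01)
  ## halving the ratio halves the count within lattice rounding
  gHalf <- buildPopulation(51108, 0.2, c(700, 700), model)
  expect_equal(nCells(gHalf) / nCells(g), 0.5, tolerance = 0.03)
  ## bad ratios
  expect_error(buildPopulation(51108, 0, c(700, 700), model), "atio")
  expect_error(buildPopulation(51108, 1.5, c(700, 700), model), "atio")
  ## all centers inside the extent
  expect_true(all(cellCenters(g) >= 0 & cellCenters(g) <= 700))
})

test_that("the rate table is deterministic, letter-driven and equivariant", {
  grid <- smallGrid(extent = 400)
  pos <- makePositionSet(c(400, 400), jitterWindowUm = 40, stepUm = 10)
  tb <- computeRateTable(grid, 100, pos, deltaTS = 0.06)
  f <- rateArray(tb)
  expect_true(all(f >= 0))
  ## a cell far from every letter position sees a blank image:
  ## rate = softplus at zero coverage
  nl <- nonlinearity(grid@model)
  corner <- which.min(rowSums(cbind(cellCenters(grid)[, 1],
                                    cellCenters(grid)[, 2])))
  expect_equal(unname(f[corner, , ]),
               matrix(softplusEval(nl, 0), nrow(pos), 4), tolerance = 1e-3)
  ## higher rate on a stroke than on background
  ctrIdx <- which(pos[, 1] == 200 & pos[, 2] == 200)
  onStroke <- which(cellCenters(grid)[, 1] == 205 &
                    cellCenters(grid)[, 2] == 205)
  expect_gt(f[onStroke, ctrIdx, 1], f[corner, ctrIdx, 1])
  ## translating both the letter and the cell by one lattice step (10 um,
  ## cells are lattice-aligned in this grid) leaves the rate unchanged
  cells <- cellCenters(grid)
  i1 <- which(cells[, 1] == 195 & cells[, 2] == 205)
  i2 <- which(cells[, 1] == 205 & cells[, 2] == 205)
  p1 <- which(pos[, 1] == 190 & pos[, 2] == 200)
  p2 <- which(pos[, 1] == 200 & pos[, 2] == 200)
  expect_equal(f[i1, p1, ], f[i2, p2, ], tolerance = 1e-9)
  ## permutation equivariance over cell order
  perm <- rev(seq_len(nCells(grid)))
  gridPerm <- new("PopulationGrid", cellCentersUm = cells[perm, ],
                  spacingUm = spacingUm(grid), extentUm = grid@extentUm,
                  model = grid@model, densityMm2 = grid@densityMm2,
                  transfectionRatio = grid@transfectionRatio)
  tbPerm <- computeRateTable(gridPerm, 100, pos, deltaTS = 0.06)
  expect_equal(rateArray(tbPerm)[perm, , ][seq_len(12), , ],
               f[seq_len(12), , ], tolerance = 1e-12)
  ## a letter that cannot fit is rejected
  expect_error(computeRateTable(grid, 390, pos), "extent too small")
})

test_that("position sequences are uniform i.i.d. draws on the set", {
  pos <- makePositionSet(c(400, 400), 100, 10)
  expect_equal(nrow(pos), 121)
  seqA <- samplePositionSequence(pos, 1, 0.067, seed = 4)
  expect_equal(nrow(seqA), 15)  # ceiling(1 / 0.067)
  expect_identical(attr(seqA, "indices"),
                   attr(samplePositionSequence(pos, 1, 0.067, seed = 4),
                        "indices"))
  ## single-element set gives a constant sequence
  one <- samplePositionSequence(pos[5, , drop = FALSE], 1, 0.1, seed = 1)
  expect_true(all(one[, 1] == pos[5, 1] & one[, 2] == pos[5, 2]))
  expect_error(samplePositionSequence(pos[0, , drop = FALSE], 1, 0.1, 1),
               "empty")
  expect_error(samplePositionSequence(pos, 1, 2, 1), "exceeds")
  ## empirical uniformity over many draws
  idx <- attr(samplePositionSequence(pos, 670, 0.067, seed = 6), "indices")
  expect_gt(chisq.test(tabulate(idx, 121))$p.value, 0.01)
})

test_that("population responses are Poisson with the tabulated rates", {
  set.seed(9)
  f <- array(runif(3 * 2 * 4, 0.5, 30), dim = c(3, 2, 4))
  tb <- toyRateTable(f, deltaTS = 0.06)
  counts <- simulatePopulationResponse(tb, 2, rep(c(1, 2), 5000), seed = 10)
  expect_equal(dim(counts), c(10000L, 3L))
  expect_identical(counts,
                   simulatePopulationResponse(tb, 2, rep(c(1, 2), 5000),
                                              seed = 10))
  ## mean of n/dt over presentations approaches f within 4 SE
  for (p in 1:2) {
    m <- colMeans(counts[seq(p, 10000, by = 2), ]) / 0.06
    se <- sqrt(f[, p, 2] / 0.06 / 5000)
    expect_true(all(abs(m - f[, p, 2]) <= 4 * se))
  }
  expect_error(simulatePopulationResponse(tb, 2, c(1, 3), seed = 1),
               "outside")
  ## vanishing presentation window: all counts zero almost surely
  tb0 <- toyRateTable(f, deltaTS = 1e-9)
  expect_true(all(simulatePopulationResponse(tb0, 1, 1:2, seed = 2) == 0))
})
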