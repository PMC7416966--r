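## The in silico tumbling-E acuity protocol and parameter sweeps.

## One decoding trial given precomputed decoder structures. Returns the
## correct/incorrect flag after each presentation.
acuityTrialCore <- function(table, dec, nPres, seed) {
  P <- nrow(table@positionsUm)
  N <- dim(table@f)[1L]
  dt <- table@deltaTS
  withSeed(seed, {
    trueLetter <- sample.int(4L, 1L)
    pidx <- sample.int(P, nPres, replace = TRUE)
    lam <- matrix(table@f[, pidx, trueLetter], nrow = N) * dt
    counts <- matrix(rpois(length(lam), lam), nrow = N)  # cells x pres
    if (dec$variant == "eq1") {
      LL <- crossprod(counts, dec$A)                     # pres x 4
      LL <- sweep(LL, 2L, dec$B, "-")
    } else {
      LL <- t(vapply(seq_len(nPres),
                     function(t) marginalUpdate(counts[, t], dec),
                     numeric(4L)))
    }
    cum <- apply(LL, 2L, cumsum)
    if (nPres == 1L) cum <- matrix(cum, nrow = 1L)
    correct <- logical(nPres)
    for (t in seq_len(nPres)) correct[t] <- decodeLetter(cum[t, ]) == trueLetter
    correct
  })
}

#' Run a single acuity trial
#'
#' Draws a random letter orientation, animates it with i.i.d. positional
#' jitter, simulates the Poisson population response, and accumulates the
#' decoder's per-presentation letter log-likelihoods, recording after every
#' presentation whether the running argmax matches the true letter.
#'
#' @param grid a [PopulationGrid-class].
#' @param sizeUm letter size, micrometers.
#' @param durationS exposure, seconds (default 1).
#' @param jitterPeriodS time per position, seconds (default 0.067).
#' @param deltaTS presentation window entering the Poisson rates, seconds
#'   (default 0.06).
#' @param decoder "eq1" (position-summed, the default) or "marginal"
#'   (position-marginalized).
#' @param seed RNG seed.
#' @param table optional precomputed [RateTable-class] for this size.
#' @param jitterWindowUm,pixelSizeUm table construction parameters, used
#'   when `table` is NULL.
#' @return logical vector: decoded correctly after presentation 1, 2, ...
#' @export
runAcuityTrial <- function(grid, sizeUm, durationS = 1,
                           jitterPeriodS = 0.067, deltaTS = 0.06,
                           decoder = c("eq1", "marginal"), seed = 1,
                           table = NULL, jitterWindowUm = 100,
                           pixelSizeUm = 10) {
  decoder <- match.arg(decoder)
  if (is.null(table)) {
    pos <- makePositionSet(grid@extentUm, jitterWindowUm, pixelSizeUm)
    table <- computeRateTable(grid, sizeUm, pos, deltaTS, pixelSizeUm)
  }
  dec <- decoderPrecompute(table, decoder)
  nPres <- ceiling(durationS / jitterPeriodS)
  acuityTrialCore(table, dec, nPres, seed)
}

#' Run the full in silico acuity test
#'
#' For each letter size, repeats the jittered-letter decoding trial
#' `nTrials` times and averages the correctness after each presentation,
#' giving success-rate curves over exposure time and letter size. The
#' acuity is the smallest size whose success rate exceeds 80 percent at the
#' end of the exposure (1 s by default), converted to Snellen notation with
#' the 25 um = 20/20 linear rule. Optional outer repetitions of the whole
#' procedure give an SD of the acuity estimate.
#'
#' @param grid a [PopulationGrid-class].
#' @param sizesUm letter sizes to test, micrometers, ascending (default: a
#'   10-point geometric ladder from 40 to 400).
#' @param nTrials trials per size (default 500).
#' @param durationS exposure, seconds (default 1).
#' @param jitterPeriodS jitter period, seconds (default 0.067).
#' @param deltaTS presentation window, seconds (default 0.06).
#' @param jitterWindowUm jitter window side, micrometers (default 100).
#' @param pixelSizeUm rendering pixel, micrometers (default 10).
#' @param decoder "eq1" or "marginal".
#' @param nRepeats outer repetitions of the whole procedure (default 1).
#' @param seed master seed; every trial derives its own sub-seed.
#' @return An [AcuityResult-class] object.
#' @export
runAcuityTest <- function(grid, sizesUm = defaultLetterSizes(),
                          nTrials = 500, durationS = 1,
                          jitterPeriodS = 0.067, deltaTS = 0.06,
                          jitterWindowUm = 100, pixelSizeUm = 10,
                          decoder = c("eq1", "marginal"), nRepeats = 1,
                          seed = 1) {
  decoder <- match.arg(decoder)
  stopIfNot(length(sizesUm) >= 1, "need at least one letter size")
  stopIfNot(!is.unsorted(sizesUm), "sizes must be ascending")
  nPres <- ceiling(durationS / jitterPeriodS)
  pos <- makePositionSet(grid@extentUm, jitterWindowUm, pixelSizeUm)
  successReps <- array(0, dim = c(length(sizesUm), nPres, nRepeats))
  for (s in seq_along(sizesUm)) {
    table <- computeRateTable(grid, sizesUm[s], pos, deltaTS, pixelSizeUm)
    dec <- decoderPrecompute(table, decoder)
    for (rep in seq_len(nRepeats)) {
      hits <- matrix(FALSE, nTrials, nPres)
      for (tr in seq_len(nTrials)) {
        trialSeed <- deriveSeed(seed, ((rep - 1L) * length(sizesUm) + s) *
                                  1000003 + tr)
        hits[tr, ] <- acuityTrialCore(table, dec, nPres, trialSeed)
      }
      successReps[s, , rep] <- colMeans(hits)
    }
  }
  success <- apply(successReps, c(1L, 2L), mean)
  acuity <- estimateAcuity(success[, nPres], sizesUm)
  sdRep <- if (nRepeats > 1) {
    acs <- vapply(seq_len(nRepeats), function(rep)
      as.numeric(estimateAcuity(successReps[, nPres, rep], sizesUm)),
      numeric(1))
    if (all(is.na(acs))) NA_real_ else sd(acs, na.rm = TRUE)
  } else NA_real_
  dimnames(success) <- list(size = sizesUm, time = seq_len(nPres))
  new("AcuityResult", success = success, sizesUm = as.numeric(sizesUm),
      timesS = seq_len(nPres) * jitterPeriodS,
      acuityUm = as.numeric(acuity),
      snellen = if (is.na(acuity)) NA_character_
                else snellenFromSize(as.numeric(acuity)),
      nTrials = as.integer(nTrials), sdOverRepeats = sdRep,
      seed = as.integer(seed))
}

#' Default letter-size ladder
#'
#' Ten sizes, geometrically spaced from 40 to 400 micrometers; the acuity
#' is always reported on the tested ladder, without interpolation.
#' @return numeric vector of sizes, micrometers.
#' @export
defaultLetterSizes <- function() {
  round(exp(seq(log(40), log(400), length.out = 10)))
}

#' Predicted acuity as a function of receptive-field size
#'
#' Rebuilds the population with each receptive-field diameter (density and
#' all other parameters fixed) and reruns the acuity test. Engineering the
#' opsin to restrict expression towards the soma shrinks the receptive
#' field; this sweep predicts the corresponding acuity gain.
#'
#' @param diametersUm receptive-field diameters (2 sigma) to test,
#'   micrometers.
#' @param config configuration list as from [defaultConfig()].
#' @param seed master seed (defaults to the config seed).
#' @return data.frame with diameter, acuity (NA = worse than the largest
#'   tested letter) and Snellen string.
#' @export
sweepRFSize <- function(diametersUm, config = defaultConfig(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (!length(diametersUm))
    return(data.frame(rf_diameter_um = numeric(0), acuity_um = numeric(0),
                      snellen = character(0)))
  rows <- lapply(seq_along(diametersUm), function(i) {
    d <- diametersUm[i]
    cfg <- config
    cfg$rf_diameter_um <- d
    res <- acuityFromConfig(cfg, seed)
    data.frame(rf_diameter_um = d, acuity_um = res@acuityUm,
               snellen = ifelse(is.na(res@acuityUm), NA_character_,
                                res@snellen))
  })
  do.call(rbind, rows)
}

#' Predicted acuity as a function of the density of reactivated cells
#'
#' Varies the transfection ratio at fixed ganglion-cell density and
#' receptive-field size. The foveal density is high enough that acuity is
#' expected to be only marginally affected down to ratios of about 10
#' percent, degrading below that.
#'
#' @param ratios transfection ratios in (0, 1].
#' @param config configuration list as from [defaultConfig()].
#' @param seed master seed (defaults to the config seed).
#' @return data.frame with ratio, acuity and Snellen string.
#' @export
sweepDensity <- function(ratios, config = defaultConfig(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  stopIfNot(all(ratios > 0 & ratios <= 1),
            "transfection ratios must be in (0, 1]")
  if (!length(ratios))
    return(data.frame(transfection_ratio = numeric(0), acuity_um = numeric(0),
                      snellen = character(0)))
  rows <- lapply(ratios, function(rt) {
    cfg <- config
    cfg$transfection_ratio <- rt
    res <- acuityFromConfig(cfg, seed)
    data.frame(transfection_ratio = rt, acuity_um = res@acuityUm,
               snellen = ifelse(is.na(res@acuityUm), NA_character_,
                                res@snellen))
  })
  do.call(rbind, rows)
}

#' Run the acuity test directly from a configuration list
#'
#' Convenience wrapper: builds the configured LN model and population grid
#' (auto-sizing the extent to the largest letter) and runs
#' [runAcuityTest()].
#'
#' @param config configuration list as from [defaultConfig()].
#' @param seed master seed (defaults to the config seed).
#' @return An [AcuityResult-class] object.
#' @export
acuityFromConfig <- function(config = defaultConfig(), seed = NULL) {
  config <- validateConfig(config)
  if (is.null(seed)) seed <- config$seed
  model <- lnModelFromConfig(config$rf_diameter_um, config$frame_rate_hz,
                             beta = config$softplus_beta,
                             theta = config$softplus_theta)
  sizes <- sort(config$letter_sizes_um)
  ext <- requiredExtentUm(max(sizes), config$jitter_window_um,
                          model@spatialSigmaUm)
  grid <- buildPopulation(config$density_mm2, config$transfection_ratio,
                          c(ext, ext), model)
  runAcuityTest(grid, sizes, nTrials = config$n_trials,
                durationS = config$duration_s,
                jitterPeriodS = config$jitter_period_s,
                deltaTS = config$delta_t_s,
                jitterWindowUm = config$jitter_window_um,
                pixelSizeUm = config$pixel_size_um,
                decoder = config$decoder_variant, seed = seed)
}
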