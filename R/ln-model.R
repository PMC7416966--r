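## Linear-nonlinear encoding model: filtering, softplus, Poisson MLE,
## prediction scoring, and the averaged population model.

#' Construct a softplus nonlinearity
#' @param alpha rate scale, Hz (>= 0).
#' @param beta gain, inverse stimulus units.
#' @param theta offset, stimulus units.
#' @return A [Softplus-class] object.
#' @export
softplus <- function(alpha, beta, theta) {
  new("Softplus", alpha = alpha, beta = beta, theta = theta)
}

#' Evaluate a softplus nonlinearity
#'
#' \eqn{r(x) = \alpha\log(1 + e^{\beta(x+\theta)})}, computed overflow-safely
#' (for large arguments the linear asymptote \eqn{\alpha\beta(x+\theta)} is
#' used through `log1p`). Non-negative everywhere; monotone increasing for
#' positive alpha and beta.
#'
#' @param p a [Softplus-class] object.
#' @param x generator-signal values.
#' @return firing rates, Hz.
#' @export
softplusEval <- function(p, x) {
  p@alpha * softplusCore(p@beta * (x + p@theta))
}

#' Construct an LN model
#'
#' @param spatialFilter spatial weight map (matrix; may be 0 x 0 when the
#'   model is specified by `spatialSigmaUm`).
#' @param temporalKernel frame-lag weights, element 1 nearest the spike.
#' @param nonlinearity a [Softplus-class].
#' @param frameRateHz frame rate, Hz.
#' @param checkSizeUm micrometers per spatial-filter pixel.
#' @param spatialSigmaUm isotropic Gaussian SD equivalent, micrometers.
#' @param inputCoding "raw01" or "centered" (see [LNModel-class]).
#' @return An [LNModel-class] object.
#' @export
lnModel <- function(spatialFilter, temporalKernel, nonlinearity, frameRateHz,
                    checkSizeUm = NA_real_, spatialSigmaUm = NA_real_,
                    inputCoding = "centered") {
  new("LNModel", spatialFilter = spatialFilter,
      temporalKernel = temporalKernel, nonlinearity = nonlinearity,
      frameRateHz = frameRateHz, checkSizeUm = checkSizeUm,
      spatialSigmaUm = spatialSigmaUm, inputCoding = inputCoding)
}

#' Filter a checkerboard stimulus through an LN model's linear stage
#'
#' Generator signal \eqn{x_t = \sum_l k_l \langle W, s_{t-l+1}\rangle}.
#' Frames are mean-centered (to -0.5/+0.5) for "centered" coding models and
#' used raw for "raw01" models. The first L-1 frames do not see a full
#' kernel window and are returned as NA (warm-up), with the warm-up length
#' in attribute `"warmup"`.
#'
#' @param model an [LNModel-class] with a spatial filter matching the
#'   stimulus check lattice.
#' @param stimulus a [CheckerboardStimulus-class].
#' @return numeric vector, one generator value per frame (NA for warm-up).
#' @export
filterStimulus <- function(model, stimulus) {
  d <- dim(stimulus@frames)
  W <- model@spatialFilter
  if (nrow(W) != d[1L] || ncol(W) != d[2L])
    stop("spatial filter dimensions do not match the stimulus", call. = FALSE)
  s <- if (model@inputCoding == "centered") stimulus@frames - 0.5
       else stimulus@frames
  M <- matrix(s, nrow = d[1L] * d[2L])
  q <- as.numeric(crossprod(as.numeric(W), M))
  k <- model@temporalKernel
  L <- length(k)
  x <- applyTemporalKernel(q, k, pad = 0)
  if (L > 1L) x[seq_len(L - 1L)] <- NA_real_
  attr(x, "warmup") <- L - 1L
  x
}

#' Fit the softplus nonlinearity by Poisson maximum likelihood
#'
#' Maximizes the Poisson log-likelihood
#' \eqn{\sum_t [n_t \log(r_t \Delta) - r_t \Delta]} over (alpha, beta,
#' theta), with \eqn{r_t} the softplus of the generator signal and
#' \eqn{\Delta} the frame-bin width. The generator is z-scored internally to
#' condition the optimizer and the scaling folded back into (beta, theta),
#' leaving the model class unchanged. Quasi-Newton (BFGS, analytic
#' gradients, alpha through a log-link to stay non-negative) with random
#' restarts.
#'
#' @param x generator signal per frame (NAs, e.g. warm-up, are dropped
#'   together with the matching counts).
#' @param counts spike counts per frame bin, aligned with `x`.
#' @param frameRateHz frame rate, Hz.
#' @param init optional [Softplus-class] initialization (on the scale of x).
#' @param nRestarts random restarts after the default initialization.
#' @param seed RNG seed for the restarts.
#' @return A [SoftplusFit-class]: parameters on the original scale of `x`,
#'   plus the final log-likelihood, scaled gradient norm and convergence.
#' @export
fitSoftplusMLE <- function(x, counts, frameRateHz, init = NULL,
                           nRestarts = 5, seed = 1) {
  keep <- !is.na(x)
  x <- x[keep]; n <- counts[keep]
  stopIfNot(length(x) == length(n), "x and counts must align")
  stopIfNot(sum(n) > 0, "all spike counts are zero; nothing to fit")
  dt <- 1 / frameRateHz
  mu <- mean(x); s <- sd(x)
  if (!is.finite(s) || s < 1e-12) { mu <- 0; s <- 1 }
  u <- (x - mu) / s

  negll <- function(par) {
    a <- exp(par[1L]); b <- par[2L]; th <- par[3L]
    r <- pmax(a * softplusCore(b * (u + th)), 1e-12)
    sum(r * dt - n * log(r * dt))
  }
  grad <- function(par) {
    a <- exp(par[1L]); b <- par[2L]; th <- par[3L]
    z <- b * (u + th)
    sp <- softplusCore(z)
    sig <- 1 / (1 + exp(-z))
    r <- pmax(a * sp, 1e-12)
    dldr <- dt - n / r
    c(sum(dldr * a * sp),
      sum(dldr * a * sig * (u + th)),
      sum(dldr * a * sig * b))
  }

  meanRate <- sum(n) / (length(n) * dt)
  starts <- list(c(log(meanRate / log(2)), 1, -median(u)))
  if (!is.null(init)) {
    ## translate an init given on the x scale to the standardized scale
    starts <- c(list(c(log(max(init@alpha, 1e-6)), init@beta * s,
                       (init@theta + mu) / s)), starts)
  }
  starts <- c(starts, withSeed(seed, lapply(seq_len(nRestarts), function(i) {
    c(log(meanRate / log(2)) + rnorm(1, 0, 0.5),
      exp(rnorm(1, 0, 0.7)), rnorm(1, 0, 1))
  })))

  best <- NULL
  for (st in starts) {
    op <- try(optim(st, negll, grad, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-12)),
              silent = TRUE)
    if (inherits(op, "try-error")) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best))
    stop("softplus MLE failed to converge after restarts", call. = FALSE)
  g <- grad(best$par)
  gradNorm <- max(abs(g)) / (1 + abs(best$value))
  aHat <- exp(best$par[1L]); bHat <- best$par[2L]; thHat <- best$par[3L]
  new("SoftplusFit",
      alpha = aHat, beta = bHat / s, theta = s * thHat - mu,
      logLik = -best$value, gradNorm = gradNorm,
      converged = best$convergence == 0L && gradNorm < 1e-4)
}

#' Predict a firing-rate trace from an LN model
#'
#' Composition of [filterStimulus()] and [softplusEval()]; warm-up frames
#' stay NA.
#'
#' @param model an [LNModel-class].
#' @param stimulus a [CheckerboardStimulus-class].
#' @return numeric rate trace, Hz per frame bin.
#' @export
predictFiringRate <- function(model, stimulus) {
  x <- filterStimulus(model, stimulus)
  r <- softplusEval(model@nonlinearity, as.numeric(x))
  attr(r, "warmup") <- attr(x, "warmup")
  r
}

#' Score a model prediction against repeated trials
#'
#' Pearson correlation between the predicted rate and the trial-averaged
#' PSTH, together with the split-half reliability of the trials on the same
#' binning (the ceiling the prediction is compared against). Warm-up NAs in
#' the prediction are excluded from both.
#'
#' @param predicted predicted rate trace (Hz per frame bin).
#' @param trials repeats x bins count matrix.
#' @param frameRateHz frame rate, Hz.
#' @return list with `pearsonR`, `reliabilityR`, `nBins`.
#' @export
scorePrediction <- function(predicted, trials, frameRateHz) {
  stopIfNot(length(predicted) == ncol(trials),
            "prediction and trials must share the binning")
  ok <- !is.na(predicted)
  psth <- colMeans(trials) * frameRateHz
  r <- if (sd(predicted[ok]) == 0 || sd(psth[ok]) == 0) NA_real_
       else cor(predicted[ok], psth[ok])
  list(pearsonR = r,
       reliabilityR = splitHalfReliability(trials[, ok, drop = FALSE]),
       nBins = sum(ok))
}

## Integer-check circular shift of a matrix (zero fill), used to re-center
## spike-triggered averages on a common origin.
shiftMatrix <- function(M, dy, dx) {
  H <- nrow(M); W <- ncol(M)
  out <- matrix(0, H, W)
  ys <- seq_len(H) - dy; xs <- seq_len(W) - dx
  okY <- ys >= 1 & ys <= H; okX <- xs >= 1 & xs <= W
  out[okY, okX] <- M[ys[okY], xs[okX]]
  out
}

#' Average LN model over selected cells
#'
#' Builds the single cell model replicated across the simulated population:
#' each cell's STA is re-centered on its fitted receptive-field center (to
#' the nearest check), the re-centered STAs are averaged, and the average is
#' decomposed into an isotropic (symmetric) spatial Gaussian and the
#' temporal course at the center. The nonlinearity is then refit by pooled
#' Poisson maximum likelihood over all cells' (generator, count) pairs —
#' refitting rather than averaging (alpha, beta, theta), because the mean of
#' softplus parameters is not the parameter of the mean model.
#'
#' @param stas list of [STA-class], one per selected cell.
#' @param fits list of converged [GaussianRFFit-class], aligned with `stas`.
#' @param stimulus the (unrepeated) [CheckerboardStimulus-class] the cells
#'   responded to.
#' @param spikesList list of spike-time vectors aligned with `stas`.
#' @return An [LNModel-class] with centered input coding; the averaged
#'   spatial map is in attribute `"averageSTA"`.
#' @export
averageCellModel <- function(stas, fits, stimulus, spikesList) {
  stopIfNot(length(stas) >= 1, "empty selection")
  stopIfNot(length(stas) == length(fits) && length(stas) == length(spikesList),
            "stas, fits and spikesList must align")
  cs <- stas[[1L]]@checkSizeUm
  d <- dim(stas[[1L]]@kernel)
  ctr <- c(ceiling(d[2L] / 2), ceiling(d[1L] / 2))  # target check (x, y)
  acc <- array(0, dim = d)
  for (i in seq_along(stas)) {
    k <- stas[[i]]@kernel
    cUm <- fits[[i]]@centerUm
    cCheck <- c(ceiling(cUm[1] / cs), ceiling(cUm[2] / cs))
    dx <- ctr[1L] - cCheck[1L]; dy <- ctr[2L] - cCheck[2L]
    for (l in seq_len(d[3L])) acc[, , l] <- acc[, , l] + shiftMatrix(k[, , l], dy, dx)
  }
  avg <- acc / length(stas)
  avgSTA <- new("STA", kernel = avg, windowMs = stas[[1L]]@windowMs,
                frameRateHz = stas[[1L]]@frameRateHz, checkSizeUm = cs,
                nSpikes = sum(vapply(stas, function(s) s@nSpikes, integer(1))))
  sp <- extractSpatialRF(avgSTA)
  fitIso <- fitGaussianRF(sp, cs, isotropic = TRUE)
  tk <- extractTemporalRF(avgSTA)
  tk <- rev(as.numeric(tk))                      # back to lag order
  tk <- tk / max(abs(tk))
  ## spatial filter: unit-sum rendered Gaussian at the fitted center
  spat <- gaussianWeightMap(fitIso@centerUm, sqrt(fitIso@sigmaXUm * fitIso@sigmaYUm),
                            d[1L], d[2L], cs)
  ## pooled nonlinearity: shared filter re-centered at each cell's position
  f <- stas[[1L]]@frameRateHz
  xAll <- numeric(0); nAll <- numeric(0)
  nBins <- dim(stimulus@frames)[3L]
  for (i in seq_along(stas)) {
    ci <- fits[[i]]@centerUm
    wi <- gaussianWeightMap(ci, sqrt(fitIso@sigmaXUm * fitIso@sigmaYUm),
                            d[1L], d[2L], cs)
    mi <- lnModel(wi, tk, softplus(1, 1, 0), f, checkSizeUm = cs,
                  inputCoding = "centered")
    xi <- filterStimulus(mi, stimulus)
    ni <- binSpikeCounts(spikesList[[i]], nBins, f)
    keep <- !is.na(xi)
    xAll <- c(xAll, xi[keep]); nAll <- c(nAll, ni[keep])
  }
  nl <- fitSoftplusMLE(xAll, nAll, f)
  out <- lnModel(spat, tk, nl, f, checkSizeUm = cs,
                 spatialSigmaUm = sqrt(fitIso@sigmaXUm * fitIso@sigmaYUm),
                 inputCoding = "centered")
  attr(out, "averageSTA") <- avgSTA
  attr(out, "isotropicFit") <- fitIso
  out
}

#' Fit a single-cell LN model from a checkerboard response
#'
#' The full estimation chain for one cell: spike-triggered average, spatial
#' and temporal receptive-field extraction, 2-D Gaussian fit, and Poisson
#' maximum-likelihood fit of the softplus nonlinearity. With
#' `denoise = TRUE` (default) the spatial filter is the unit-sum Gaussian
#' rendered from the fit rather than the raw STA slice, which removes
#' estimation noise in checks far from the receptive field.
#'
#' @param stimulus a [CheckerboardStimulus-class].
#' @param spikes spike-time vector, seconds.
#' @param windowMs STA window, ms.
#' @param denoise use the fitted Gaussian as the spatial filter.
#' @return list with `model` ([LNModel-class]), `sta`, `fit`
#'   ([GaussianRFFit-class]) and `nonlinearityFit` ([SoftplusFit-class]).
#' @export
fitCellLNModel <- function(stimulus, spikes, windowMs = 200, denoise = TRUE) {
  sta <- computeSTA(stimulus, spikes, windowMs)
  srf <- extractSpatialRF(sta)
  trf <- extractTemporalRF(sta)
  fit <- fitGaussianRF(srf, stimulus@checkSizeUm)
  tk <- rev(as.numeric(trf))
  tk <- tk / max(abs(tk))
  d <- dim(sta@kernel)
  spat <- if (denoise && fit@converged) {
    gaussianWeightMap(fit@centerUm, sqrt(fit@sigmaXUm * fit@sigmaYUm),
                      d[1L], d[2L], stimulus@checkSizeUm)
  } else {
    srfPlain <- srf; attributes(srfPlain) <- list(dim = dim(srf))
    srfPlain / sum(srfPlain)
  }
  probe <- lnModel(spat, tk, softplus(1, 1, 0), stimulus@frameRateHz,
                   checkSizeUm = stimulus@checkSizeUm,
                   inputCoding = "centered")
  x <- filterStimulus(probe, stimulus)
  n <- binSpikeCounts(spikes, dim(stimulus@frames)[3L],
                      stimulus@frameRateHz)
  nl <- fitSoftplusMLE(x, n, stimulus@frameRateHz)
  model <- lnModel(spat, tk, nl, stimulus@frameRateHz,
                   checkSizeUm = stimulus@checkSizeUm,
                   spatialSigmaUm = if (fit@converged)
                     sqrt(fit@sigmaXUm * fit@sigmaYUm) else NA_real_,
                   inputCoding = "centered")
  list(model = model, sta = sta, fit = fit, nonlinearityFit = nl)
}

#' LN model specified by configuration parameters
#'
#' The population cell used for acuity simulation when no recordings are
#' being averaged: an isotropic Gaussian receptive field of a given
#' 2-sigma diameter plus a softplus on the raw \{0,1\} luminance scale,
#' with the default 50 Hz full-ink calibration of [groundTruthCell()].
#'
#' @param rfDiameterUm receptive-field diameter (2 sigma), micrometers.
#' @param frameRateHz frame rate, Hz.
#' @param alpha,beta,theta softplus parameters (`alpha = NULL` applies the
#'   50 Hz calibration).
#' @return An [LNModel-class] with raw01 coding and a unit-DC temporal
#'   kernel.
#' @export
lnModelFromConfig <- function(rfDiameterUm = 82, frameRateHz = 30,
                              alpha = NULL, beta = 10, theta = -0.5) {
  if (is.null(alpha)) alpha <- 50 / softplusCore(beta * (1 + theta))
  lnModel(matrix(numeric(0), 0, 0), defaultTemporalKernel(frameRateHz),
          softplus(alpha, beta, theta), frameRateHz,
          spatialSigmaUm = rfDiameterUm / 2, inputCoding = "raw01")
}
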