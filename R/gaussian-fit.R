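## 2-D Gaussian receptive-field fitting and bootstrap uncertainty.

## Elliptical Gaussian surface with baseline, evaluated on (x, y) vectors.
gauss2dSurface <- function(x, y, x0, y0, sx, sy, phi, A, b) {
  ct <- cos(phi); st <- sin(phi)
  u <- (x - x0) * ct + (y - y0) * st
  v <- -(x - x0) * st + (y - y0) * ct
  b + A * exp(-0.5 * (u^2 / sx^2 + v^2 / sy^2))
}

#' Fit a two-dimensional Gaussian to a spatial receptive field
#'
#' Least-squares fit of `baseline + amplitude * exp(-quadratic form)` with
#' free center, anisotropic SDs and orientation (Levenberg-Marquardt with
#' box constraints). The receptive-field diameter is reported as
#' \eqn{2\sqrt{\sigma_x \sigma_y}} in micrometers: the diameter of the
#' circle matching the area of the 1-SD ellipse. SDs are constrained to
#' \[0.25, 10\] checks and the center to the stimulated area padded by two
#' checks; a fit pinned at those bounds is flagged non-converged.
#'
#' The `rfVisible` flag requires a converged fit whose amplitude stands at
#' least five noise SDs above the floor, the noise SD being estimated from
#' map values farther than three fitted sigmas from the center (over 99
#' percent of the Gaussian mass excluded), falling back to the residual SD
#' when too few far checks exist.
#'
#' @param spatialRF H x W map, e.g. from [extractSpatialRF()].
#' @param checkSizeUm micrometers per check.
#' @param isotropic force sigmaX = sigmaY (used for the population-average
#'   receptive field, which is modelled as symmetric).
#' @return A [GaussianRFFit-class] object (`diameterSeUm` is NA until
#'   [bootstrapRFError()] is run).
#' @export
fitGaussianRF <- function(spatialRF, checkSizeUm, isotropic = FALSE) {
  H <- nrow(spatialRF); W <- ncol(spatialRF)
  if (max(abs(spatialRF)) == 0)
    stop("map has no nonzero extremum", call. = FALSE)
  xs <- (seq_len(W) - 0.5) * checkSizeUm
  ys <- (seq_len(H) - 0.5) * checkSizeUm
  gridXY <- expand.grid(y = ys, x = xs)   # column-major to match as.vector
  z <- as.vector(spatialRF)
  b0 <- median(z)
  pk <- which.max(abs(z - b0))
  A0 <- z[pk] - b0
  x0 <- gridXY$x[pk]; y0 <- gridXY$y[pk]
  s0 <- 1.5 * checkSizeUm
  loS <- 0.25 * checkSizeUm; hiS <- 10 * checkSizeUm
  loC <- -2 * checkSizeUm
  hiX <- W * checkSizeUm + 2 * checkSizeUm
  hiY <- H * checkSizeUm + 2 * checkSizeUm

  xg <- gridXY$x; yg <- gridXY$y
  residFun <- if (isotropic) {
    function(par) z - gauss2dSurface(xg, yg, par["x0"], par["y0"],
                                     par["s"], par["s"], 0,
                                     par["A"], par["b"])
  } else {
    function(par) z - gauss2dSurface(xg, yg, par["x0"], par["y0"],
                                     par["sx"], par["sy"], par["phi"],
                                     par["A"], par["b"])
  }
  if (isotropic) {
    start <- c(x0 = x0, y0 = y0, s = s0, A = A0, b = b0)
    lower <- c(loC, loC, loS, -Inf, -Inf)
    upper <- c(hiX, hiY, hiS, Inf, Inf)
  } else {
    start <- c(x0 = x0, y0 = y0, sx = s0, sy = s0, phi = 0, A = A0, b = b0)
    lower <- c(loC, loC, loS, loS, -pi, -Inf, -Inf)
    upper <- c(hiX, hiY, hiS, hiS, pi, Inf, Inf)
  }
  fit <- try(minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = residFun,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)

  bad <- inherits(fit, "try-error") || !fit$info %in% 1:4
  if (!bad) {
    p <- as.list(fit$par)
    if (isotropic) { p$sx <- p$s; p$sy <- p$s; p$phi <- 0 }
    eps <- 1e-4 * checkSizeUm
    pinned <- p$sx < loS + eps || p$sx > hiS - eps ||
      p$sy < loS + eps || p$sy > hiS - eps
    resid <- z - gauss2dSurface(gridXY$x, gridXY$y, p$x0, p$y0,
                                p$sx, p$sy, p$phi, p$A, p$b)
    converged <- !pinned
    ## noise floor from checks far from the fitted center
    sg <- sqrt(p$sx * p$sy)
    far <- sqrt((gridXY$x - p$x0)^2 + (gridXY$y - p$y0)^2) > 3 * sg
    noiseSd <- if (sum(far) >= 8) sd(z[far]) else sd(resid)
    visible <- converged &&
      (noiseSd == 0 && abs(p$A) > 0 || abs(p$A) > 5 * noiseSd)
    new("GaussianRFFit",
        centerUm = c(p$x0, p$y0), sigmaXUm = p$sx, sigmaYUm = p$sy,
        phiRad = p$phi, amplitude = p$A, baseline = p$b,
        diameterUm = 2 * sqrt(p$sx * p$sy), diameterSeUm = NA_real_,
        fitResidual = sqrt(mean(resid^2)), converged = converged,
        rfVisible = visible)
  } else {
    new("GaussianRFFit",
        centerUm = c(NA_real_, NA_real_), sigmaXUm = NA_real_,
        sigmaYUm = NA_real_, phiRad = NA_real_, amplitude = NA_real_,
        baseline = NA_real_, diameterUm = NA_real_, diameterSeUm = NA_real_,
        fitResidual = NA_real_, converged = FALSE, rfVisible = FALSE)
  }
}

#' Bootstrap standard error of the receptive-field diameter
#'
#' The coarse check size leaves residual noise in the spike-triggered
#' average; this quantifies its effect on the fitted diameter. Gaussian
#' noise with zero mean and variance matching the STA far from the cell
#' center (beyond three fitted sigmas) is added to the denoised fitted
#' surface; refitting each corrupted map gives a distribution of diameters
#' whose SD is the reported error.
#'
#' @param fit a converged [GaussianRFFit-class].
#' @param spatialRF the H x W map the fit was computed from.
#' @param checkSizeUm micrometers per check.
#' @param nBoot bootstrap replicates (>= 100).
#' @param seed integer RNG seed.
#' @return the input fit with `diameterSeUm` filled in; the replicate
#'   diameters are in attribute `"bootDiameters"`.
#' @export
bootstrapRFError <- function(fit, spatialRF, checkSizeUm, nBoot = 500,
                             seed = 1) {
  stopIfNot(fit@converged, "fit must have converged")
  stopIfNot(nBoot >= 100, "nBoot must be >= 100")
  H <- nrow(spatialRF); W <- ncol(spatialRF)
  xs <- rep((seq_len(W) - 0.5) * checkSizeUm, each = H)
  ys <- rep((seq_len(H) - 0.5) * checkSizeUm, times = W)
  sg <- sqrt(fit@sigmaXUm * fit@sigmaYUm)
  far <- sqrt((xs - fit@centerUm[1])^2 + (ys - fit@centerUm[2])^2) > 3 * sg
  if (sum(far) < 8)
    stop("too few checks beyond 3 sigma to estimate the noise variance",
         call. = FALSE)
  noiseSd <- sd(as.vector(spatialRF)[far])
  surface <- matrix(
    gauss2dSurface(xs, ys, fit@centerUm[1], fit@centerUm[2],
                   fit@sigmaXUm, fit@sigmaYUm, fit@phiRad,
                   fit@amplitude, fit@baseline), nrow = H)
  ds <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      noisy <- surface + matrix(rnorm(H * W, 0, noiseSd), nrow = H)
      rf <- fitGaussianRF(noisy, checkSizeUm)
      if (rf@converged) rf@diameterUm else NA_real_
    }, numeric(1))
  })
  ds <- ds[!is.na(ds)]
  fit@diameterSeUm <- if (noiseSd == 0) 0 else sd(ds)
  attr(fit, "bootDiameters") <- ds
  fit
}
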