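## Spike-triggered average receptive-field estimation.

#' Compute the spike-triggered average
#'
#' Averages the mean-centered stimulus frames (values -0.5/+0.5) in a time
#' window preceding each spike, producing a 3-d receptive-field estimate:
#' two dimensions of space, one of time. A spike falling in frame bin k
#' (half-open bins \[k/f, (k+1)/f)) triggers frames k, k-1, ..., k-L+1 at
#' lags 1..L; spikes earlier than the first full window are discarded.
#'
#' @param stimulus a [CheckerboardStimulus-class].
#' @param spikes numeric vector of spike times (s), or a
#'   [SpikeTrains-class] plus `cell` to pick one train.
#' @param windowMs averaging window, ms (default 200).
#' @param cell cell name/index when `spikes` is a SpikeTrains object.
#' @return An [STA-class] object.
#' @export
computeSTA <- function(stimulus, spikes, windowMs = 200, cell = NULL) {
  if (is(spikes, "SpikeTrains"))
    spikes <- if (is.null(cell)) spikes@spikes[[1L]] else spikes@spikes[[cell]]
  d <- dim(stimulus@frames)
  f <- stimulus@frameRateHz
  L <- round(windowMs * f / 1000)
  stopIfNot(L >= 1, "window shorter than one frame")
  stopIfNot(L <= d[3L], "window longer than the recording")
  counts <- binSpikeCounts(spikes, d[3L], f)
  usable <- seq_len(d[3L]) >= L
  n <- sum(counts[usable])
  stopIfNot(n >= 1, "no usable spikes after the first full window")
  w <- counts
  w[!usable] <- 0L
  M <- matrix(stimulus@frames - 0.5, nrow = d[1L] * d[2L])
  kern <- array(0, dim = c(d[1L], d[2L], L))
  tIdx <- which(w > 0L)
  wt <- w[tIdx]
  for (l in seq_len(L)) {
    kern[, , l] <- matrix(M[, tIdx - l + 1L, drop = FALSE] %*% wt / n,
                          nrow = d[1L])
  }
  new("STA", kernel = kern, windowMs = windowMs, frameRateHz = f,
      checkSizeUm = stimulus@checkSizeUm, nSpikes = as.integer(n))
}

#' Extract the spatial receptive field from an STA
#'
#' Returns the temporal slice of the STA containing the global extremum of
#' the whole kernel. The extremum is taken in absolute value so the same
#' slice is selected for sign-inverted kernels; optogenetically reactivated
#' cells are ON-like, but the rule stays robust to contrast conventions.
#'
#' @param sta an [STA-class] object.
#' @return H x W numeric map (stimulus units), with the selected lag in
#'   attribute `"lag"`.
#' @export
extractSpatialRF <- function(sta) {
  k <- sta@kernel
  if (all(k == 0)) stop("all-zero STA: no receptive field", call. = FALSE)
  pk <- which(abs(k) == max(abs(k)), arr.ind = TRUE)[1L, ]
  out <- k[, , pk[3L]]
  attr(out, "lag") <- unname(pk[3L])
  attr(out, "peakCheck") <- unname(pk[1:2])
  out
}

#' Extract the temporal receptive field from an STA
#'
#' Time course of the STA at the check holding the global extremum, ordered
#' from the earliest lag to the spike time (the conventional plotting order,
#' -window ... 0 ms).
#'
#' @param sta an [STA-class] object.
#' @return numeric vector of length L, earliest lag first; lag-bin times
#'   (ms before the spike, negative) in attribute `"timesMs"`.
#' @export
extractTemporalRF <- function(sta) {
  k <- sta@kernel
  if (all(k == 0)) stop("all-zero STA: no receptive field", call. = FALSE)
  pk <- which(abs(k) == max(abs(k)), arr.ind = TRUE)[1L, ]
  v <- rev(k[pk[1L], pk[2L], ])
  L <- length(v)
  attr(v, "timesMs") <- -rev((seq_len(L) - 0.5) / sta@frameRateHz * 1000)
  v
}

#' Peak-response latency interval
#'
#' The frame rate limits temporal resolution, so the latency is an interval:
#' a peak in lag bin k (bin 1 nearest the spike) places the response onset
#' between (k-1)/f and k/f. At 40 Hz a bin-2 peak means a latency between
#' 25 and 50 ms; a bin-1 peak at 30 Hz means below 33.3 ms.
#'
#' @param temporalRF temporal receptive field as returned by
#'   [extractTemporalRF()] (earliest lag first).
#' @param frameRateHz stimulus frame rate, Hz.
#' @return numeric length-2 vector, half-open interval \[lo, hi) in ms.
#' @export
peakLatency <- function(temporalRF, frameRateHz) {
  stopIfNot(length(temporalRF) >= 1, "empty temporal receptive field")
  L <- length(temporalRF)
  kBin <- L + 1L - which.max(abs(temporalRF))  # 1 = nearest the spike
  c(lo = (kBin - 1) / frameRateHz * 1000, hi = kBin / frameRateHz * 1000)
}

#' Split-half response reliability
#'
#' Splits the repeated trials into odd- and even-indexed halves (interleaved
#' so slow drift cancels), computes the PSTH of each half, and returns the
#' Pearson correlation between the two. Cells whose reliability exceeds 0.5
#' pass the selection used throughout the analysis.
#'
#' @param trials numeric matrix, repeats x time bins, spike counts.
#' @return Pearson r, or NA (flagged non-reliable) when either half-PSTH is
#'   constant.
#' @export
splitHalfReliability <- function(trials) {
  stopIfNot(nrow(trials) >= 2, "need at least two repeats")
  odd <- seq(1L, nrow(trials), by = 2L)
  even <- seq(2L, nrow(trials), by = 2L)
  p1 <- colMeans(trials[odd, , drop = FALSE])
  p2 <- colMeans(trials[even, , drop = FALSE])
  if (sd(p1) == 0 || sd(p2) == 0) return(NA_real_)
  cor(p1, p2)
}

#' Select cells with a visible receptive field and reliable responses
#'
#' A cell is kept iff it has a visible receptive field and its split-half
#' reliability is strictly larger than the threshold (a cell at exactly the
#' threshold is rejected).
#'
#' @param qc data.frame with columns `cell_id`, `rf_visible` (logical) and
#'   `reliability_r` (numeric, NA allowed and treated as failing).
#' @param threshold reliability threshold (default 0.5).
#' @return character/whatever vector of selected `cell_id`s (possibly empty).
#' @export
selectCells <- function(qc, threshold = 0.5) {
  if (nrow(qc) == 0L) return(qc$cell_id)
  keep <- qc$rf_visible & !is.na(qc$reliability_r) &
    qc$reliability_r > threshold
  qc$cell_id[keep]
}

#' Population summary of receptive-field diameters
#'
#' Inverse-variance weighted mean of the per-cell diameters (weights
#' 1/SE^2), with the SEM across cells. If any bootstrap SE is exactly zero
#' while others are not, the weights are undefined and the function falls
#' back to the unweighted mean with a warning.
#'
#' @param fits list of [GaussianRFFit-class] objects (converged, >= 2).
#' @return list with `meanDiameterUm`, `semUm`, `n`, `weighted`.
#' @export
populationRFSummary <- function(fits) {
  stopIfNot(length(fits) >= 2, "need at least two converged fits")
  d <- vapply(fits, function(f) f@diameterUm, numeric(1))
  se <- vapply(fits, function(f) f@diameterSeUm, numeric(1))
  weighted <- TRUE
  if (any(is.na(se))) stop("bootstrap SEs missing; run bootstrapRFError first",
                           call. = FALSE)
  if (any(se == 0) && any(se > 0)) {
    warning("zero bootstrap SE for some cells; using unweighted mean")
    weighted <- FALSE
  }
  m <- if (weighted && all(se > 0)) {
    w <- 1 / se^2
    sum(w * d) / sum(w)
  } else mean(d)
  list(meanDiameterUm = m, semUm = sd(d) / sqrt(length(d)),
       n = length(d), weighted = weighted && all(se > 0))
}
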