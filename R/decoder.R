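## Bayesian ideal-observer letter decoding from population spike counts.

## Rate floor (Hz) applied before taking logs. The softplus is strictly
## positive so this only guards degenerate configurations (e.g. alpha = 0).
.RATE_FLOOR <- 1e-6

#' Per-presentation letter log-likelihoods (position-summed decoder)
#'
#' For the observed population counts n of a single presentation, and for
#' each candidate letter, the score
#' \deqn{L(\ell) = \sum_{p,i} [ n_i \log f(i,p,\ell) - \Delta t\, f(i,p,\ell) ]}
#' summed over all candidate positions p and cells i, with the
#' letter-independent constant set to zero. This is the default decoder:
#' position uncertainty enters by summing the log-likelihood over
#' positions.
#'
#' @param counts integer vector of spike counts, one per cell.
#' @param table a [RateTable-class].
#' @return numeric length-4 vector of log-likelihood scores (nats).
#' @export
eq1LetterLoglik <- function(counts, table) {
  stopIfNot(all(counts >= 0), "counts must be non-negative")
  stopIfNot(length(counts) == dim(table@f)[1L],
            "one count per cell required")
  dec <- decoderPrecompute(table, "eq1")
  as.numeric(counts %*% dec$A - dec$B)
}

#' Per-presentation letter log-likelihoods (position-marginalized decoder)
#'
#' The proper Bayesian treatment of the unknown letter position: the Poisson
#' likelihood is averaged (not summed in log space) over positions,
#' \deqn{L(\ell) = \mathrm{logsumexp}_p\big[\textstyle\sum_i n_i \log(f\Delta t)
#'   - \Delta t f - \log n_i!\big] - \log P.}
#' With a single candidate position the two decoders agree up to a
#' letter-independent constant.
#'
#' @inheritParams eq1LetterLoglik
#' @return numeric length-4 vector of marginal log-likelihoods (nats).
#' @export
marginalLetterLoglik <- function(counts, table) {
  stopIfNot(all(counts >= 0), "counts must be non-negative")
  stopIfNot(length(counts) == dim(table@f)[1L],
            "one count per cell required")
  dec <- decoderPrecompute(table, "marginal")
  marginalUpdate(counts, dec)
}

## Precompute the per-letter structures the per-presentation updates need.
## eq1:      A (cells x 4) = sum_p log f, B (4) = dt * sum_{p,i} f
## marginal: logF (list of cells x P log(f*dt)), colF (P x 4) = dt*sum_i f
decoderPrecompute <- function(table, variant = c("eq1", "marginal")) {
  variant <- match.arg(variant)
  f <- pmax(table@f, .RATE_FLOOR)
  dt <- table@deltaTS
  d <- dim(f)
  if (variant == "eq1") {
    lf <- log(f)
    A <- vapply(seq_len(d[3L]),
                function(ell) rowSums(lf[, , ell, drop = FALSE][, , 1, drop = FALSE]),
                numeric(d[1L]))
    B <- dt * vapply(seq_len(d[3L]), function(ell) sum(f[, , ell]), numeric(1))
    list(variant = "eq1", A = A, B = B)
  } else {
    logF <- lapply(seq_len(d[3L]), function(ell) log(f[, , ell] * dt))
    colF <- dt * vapply(seq_len(d[3L]),
                        function(ell) colSums(matrix(f[, , ell], d[1L])),
                        numeric(d[2L]))
    list(variant = "marginal", logF = logF, colF = matrix(colF, ncol = d[3L]),
         logP = log(d[2L]))
  }
}

marginalUpdate <- function(counts, dec) {
  lfact <- sum(lfactorial(counts))
  vapply(seq_along(dec$logF), function(ell) {
    perPos <- as.numeric(counts %*% dec$logF[[ell]]) - dec$colF[, ell] - lfact
    logSumExp(perPos) - dec$logP
  }, numeric(1))
}

#' Decode the letter from accumulated evidence
#'
#' Argmax of the cumulative log-likelihood vector; exact ties are broken
#' uniformly at random with the caller's RNG stream.
#'
#' @param cumLoglik numeric length-4 vector of accumulated log-likelihoods.
#' @return letter index 1..4.
#' @export
decodeLetter <- function(cumLoglik) {
  stopIfNot(length(cumLoglik) >= 1, "no accumulated evidence")
  best <- which(cumLoglik == max(cumLoglik))
  if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
  best
}
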