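## Internal numerical helpers shared across modules.

#' @importFrom stats rbinom rpois rnorm runif sd cor median optim convolve
#'   coef setNames
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library functions never clobber the
#' caller's RNG stream. A `NULL` seed means "use the current stream".
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

## Deterministic sub-seed derivation: one master seed per run, one derived
## seed per (operation, index). Kept below 2^31 - 1.
deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) + 104729 * as.double(k)) %% 2147483647)
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Overflow-safe softplus log(1 + exp(z)).
softplusCore <- function(z) {
  out <- z                                # NAs (e.g. warm-up) pass through
  pos <- which(z > 0)
  neg <- which(z <= 0)
  out[pos] <- z[pos] + log1p(exp(-z[pos]))
  out[neg] <- log1p(exp(z[neg]))
  out
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## 1-D convolution of each column of M with a centered odd-length kernel g,
## zero padding at the edges. Used (twice, transposed) for the separable
## Gaussian smoothing of letter images.
convColumns <- function(M, g) {
  K <- (length(g) - 1L) %/% 2L
  n <- nrow(M)
  gr <- rev(g)
  apply(M, 2L, function(col) {
    v <- convolve(col, gr, type = "open")
    v[(K + 1L):(K + n)]
  })
}

sepConv2 <- function(img, gx, gy) {
  ## img rows index y, cols index x; gy smooths along rows, gx along cols
  t(convColumns(t(convColumns(img, gy)), gx))
}

## Vectorized bilinear interpolation on a regular grid of cell centers.
## S[yi, xi] holds values at x = x0 + (xi-1)*dx, y = y0 + (yi-1)*dy.
## Queries outside the grid return `outside` (the smoothed letter images
## used here decay to zero well inside the canvas).
bilinearInterp <- function(S, x0, dx, y0, dy, xq, yq, outside = 0) {
  nx <- ncol(S); ny <- nrow(S)
  gx <- (xq - x0) / dx + 1
  gy <- (yq - y0) / dy + 1
  j0 <- floor(gx); i0 <- floor(gy)
  fx <- gx - j0; fy <- gy - i0
  ok <- j0 >= 1 & j0 <= nx - 1 & i0 >= 1 & i0 <= ny - 1
  out <- rep(outside, length(xq))
  if (any(ok)) {
    j0k <- j0[ok]; i0k <- i0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
    v00 <- S[cbind(i0k, j0k)]
    v01 <- S[cbind(i0k, j0k + 1)]
    v10 <- S[cbind(i0k + 1, j0k)]
    v11 <- S[cbind(i0k + 1, j0k + 1)]
    out[ok] <- v00 * (1 - fxk) * (1 - fyk) + v01 * fxk * (1 - fyk) +
      v10 * (1 - fxk) * fyk + v11 * fxk * fyk
  }
  ## boundary rows/columns: clamp exact hits on the last grid line
  edge <- !ok & gx >= 1 & gx <= nx & gy >= 1 & gy <= ny
  if (any(edge)) {
    je <- pmin(pmax(round(gx[edge]), 1), nx)
    ie <- pmin(pmax(round(gy[edge]), 1), ny)
    out[edge] <- S[cbind(ie, je)]
  }
  out
}
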