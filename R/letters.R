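## Tumbling-E optotype rendering and acuity bookkeeping.

## Membership test of points in the base (opening-right) 5x5 "E" glyph:
## coordinates (xi, eta) in [0, s) x [0, s), stroke u = s/5; ink is the
## left spine plus three full-width bars (rows 1, 3, 5 from the bottom).
## Half-open boundaries keep pixel-center rasterization exact.
eGlyphBase <- function(xi, eta, s) {
  u <- s / 5
  inside <- xi >= 0 & xi < s & eta >= 0 & eta < s
  ink <- xi < u | eta < u | (eta >= 2 * u & eta < 3 * u) | eta >= 4 * u
  inside & ink
}

#' Render a tumbling-E letter stimulus
#'
#' Rasterizes the standard 5x5 optotype E (stroke width = size/5, white
#' letter on black background) by pixel-center coverage on a canvas with
#' lower-left origin. Orientations are exact 90-degree rotations of the
#' glyph: "right", "up", "left", "down" name the direction the three arms
#' open towards.
#'
#' @param sizeUm letter height, micrometers (must be at least 2 pixels).
#' @param orientation one of "right", "up", "left", "down", or 1..4.
#' @param positionUm letter-center position (x, y), micrometers.
#' @param pixelSizeUm rendering pixel, micrometers.
#' @param canvasUm canvas extent (width, height), micrometers.
#' @return 0/1 matrix (rows index y bottom-up, columns x), with rendering
#'   metadata in attributes.
#' @export
renderLetterE <- function(sizeUm, orientation, positionUm, pixelSizeUm,
                          canvasUm) {
  stopIfNot(sizeUm >= 2 * pixelSizeUm,
            "letter smaller than two pixels cannot be resolved")
  if (is.character(orientation))
    orientation <- match(match.arg(orientation, letterOrientations()),
                         letterOrientations())
  stopIfNot(orientation %in% 1:4, "orientation must be one of 1..4")
  s <- sizeUm
  if (positionUm[1] - s / 2 < 0 || positionUm[1] + s / 2 > canvasUm[1] ||
      positionUm[2] - s / 2 < 0 || positionUm[2] + s / 2 > canvasUm[2])
    stop("letter does not fit on the canvas at this position", call. = FALSE)
  W <- round(canvasUm[1] / pixelSizeUm)
  H <- round(canvasUm[2] / pixelSizeUm)
  px <- (seq_len(W) - 0.5) * pixelSizeUm
  py <- (seq_len(H) - 0.5) * pixelSizeUm
  ax <- rep(px, each = H) - positionUm[1]   # column-major over (y, x)
  ay <- rep(py, times = W) - positionUm[2]
  ## rotate the query points into base-glyph coordinates: a CCW glyph
  ## rotation is a CW point rotation, (a, b) -> (b, -a), applied k times
  k <- (orientation - 1L) %% 4L
  for (i in seq_len(k)) {
    tmp <- ax; ax <- ay; ay <- -tmp
  }
  img <- matrix(as.numeric(eGlyphBase(ax + s / 2, ay + s / 2, s)), nrow = H)
  attr(img, "sizeUm") <- sizeUm
  attr(img, "orientation") <- letterOrientations()[orientation]
  attr(img, "positionUm") <- positionUm
  attr(img, "pixelSizeUm") <- pixelSizeUm
  img
}

#' The four tumbling-E orientations
#' @return character vector: direction the arms open towards.
#' @export
letterOrientations <- function() c("right", "up", "left", "down")

#' Read the acuity off a success-rate table
#'
#' Applies the strict rule used in the simulated test: the acuity is the
#' smallest tested letter size whose success rate is strictly larger than
#' 80 percent after the full exposure. Exactly 80 percent does not qualify.
#'
#' @param success success fractions at the final time, one per size.
#' @param sizesUm tested letter sizes, ascending.
#' @return the acuity in micrometers, or NA with attribute
#'   `"status" = "worse than max tested"` when no size qualifies.
#' @export
estimateAcuity <- function(success, sizesUm) {
  stopIfNot(!is.unsorted(sizesUm), "sizes must be sorted ascending")
  stopIfNot(length(success) == length(sizesUm),
            "one success value per size required")
  ok <- which(success > 0.80)
  if (!length(ok)) {
    out <- NA_real_
    attr(out, "status") <- "worse than max tested"
    return(out)
  }
  sizesUm[min(ok)]
}

#' Convert a letter size to Snellen notation
#'
#' Anchored to the convention that discriminating a 25 um letter
#' corresponds to 20/20, with linear scaling: 20/D, D = round(20 * size/25).
#' 250 um maps to 20/200, the legal-blindness denominator.
#'
#' @param sizeUm letter size, micrometers (> 0).
#' @return Snellen string "20/D".
#' @export
snellenFromSize <- function(sizeUm) {
  stopIfNot(all(sizeUm > 0), "size must be positive")
  paste0("20/", round(20 * sizeUm / 25))
}
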