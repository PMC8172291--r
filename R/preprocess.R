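# Contrast enhancement of the green channel: CLAHE followed by a gamma
# transformation. CLAHE raises local vessel/background contrast; the gamma
# step (gamma > 1) darkens the mid-tone background relative to bright
# structures, suppressing residual background noise.

#' Preprocessing configuration
#'
#' @param claheClip CLAHE clip limit (> 0); higher values allow stronger
#'   local amplification. `Inf` effectively disables clipping.
#' @param claheTiles integer vector `c(rows, cols)` of CLAHE tiles.
#' @param gamma exponent of the gamma transformation (> 0).
#' @return list of class `preprocessConfig`.
#' @export
preprocessConfig <- function(claheClip = 2, claheTiles = c(8, 8), gamma = 1.2) {
  if (claheClip <= 0 || gamma <= 0 || any(claheTiles < 1))
    stop("preprocess parameters must be strictly positive")
  structure(list(claheClip = claheClip, claheTiles = as.integer(claheTiles),
                 gamma = gamma), class = "preprocessConfig")
}

#' Contrast-limited adaptive histogram equalization
#'
#' @param g grayscale matrix on 0-255.
#' @param cfg a [preprocessConfig()].
#' @return matrix on 0-255.
#' @export
claheEnhance <- function(g, cfg = preprocessConfig()) {
  stopifnotMatrix(g)
  if (nrow(g) < cfg$claheTiles[1] || ncol(g) < cfg$claheTiles[2])
    stop("image smaller than the CLAHE tile grid")
  if (max(g) == min(g)) return(g)  # nothing to equalize
  out <- EBImage::clahe(EBImage::Image(t(g) / 255),
                        nx = cfg$claheTiles[2], ny = cfg$claheTiles[1],
                        limit = cfg$claheClip)
  clip255(t(as.matrix(EBImage::imageData(out))) * 255)
}

#' Gamma transformation
#'
#' Elementwise `255 * (g / 255)^gamma`; monotone non-decreasing in the input
#' for any positive gamma, fixing 0 and 255.
#'
#' @param g grayscale matrix on 0-255.
#' @param gamma exponent, `> 0`.
#' @return matrix on 0-255.
#' @examples
#' gammaCorrect(matrix(128), gamma = 2)  # 255 * (128/255)^2 = 64.25...
#' @export
gammaCorrect <- function(g, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("gamma must be a single value > 0")
  stopifnotMatrix(g)
  255 * (g / 255)^gamma
}

#' Full preprocessing pipeline
#'
#' `gammaCorrect(claheEnhance(extractGreen(img)))` — green-channel
#' extraction, CLAHE, then gamma correction, all deterministic and
#' dimension-preserving.
#'
#' @param img H x W x 3 fundus array.
#' @param cfg a [preprocessConfig()].
#' @return grayscale matrix on 0-255.
#' @export
preprocessFundus <- function(img, cfg = preprocessConfig()) {
  gammaCorrect(claheEnhance(extractGreen(img), cfg), cfg$gamma)
}
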