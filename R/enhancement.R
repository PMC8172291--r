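# The three channel-specific enhancement pipelines.
#
# Channel 1 removes the slowly varying background (optic disc, uneven
# illumination) with a grayscale closing: the closing estimates the
# background, the vessel-sized dark detail is the difference, and the result
# is recentred and min-max rescaled to 0-255.
#
# Channels 2 and 3 correlate the image with a bank of rotated inverted-
# Gaussian line templates (large scale for thick vessels, small scale for
# thin ones), take the pixelwise best orientation, rescale to 0-255, and
# then apply the inverted double black-hat transform to suppress background
# left by the filtering.

#' Closing-based background removal
#'
#' Computes the grayscale closing `I_close` of the image with a disc of the
#' given radius, forms `255 - (I_close - I) + mean(I_close)` and min-max
#' rescales the result to `[0, 255]`. Dark vessel-scale structure (removed
#' by the closing) ends up dark against a flattened bright background.
#'
#' @param g grayscale matrix on 0-255.
#' @param discRadius closing disc radius in pixels (default 11).
#' @return matrix on 0-255; a constant input returns all zeros with a
#'   degenerate-input warning.
#' @export
removeBackgroundClose <- function(g, discRadius = 11) {
  stopifnotMatrix(g)
  icl <- closeDisc(g, discRadius)
  raw <- 255 - (icl - g) + mean(icl)
  rescale255(raw)
}

#' Build a rotated matched-filter bank
#'
#' Constructs `nDirs` rotated copies of the canonical inverted-Gaussian line
#' template (see [KernelBank-class]). Orientation `i` uses angle
#' `(i-1) * pi / nDirs`. Template support: `|u| <= max(3 s, 1)` across the
#' line and `|v| <= l / 2` along it; the across-line half-width is floored
#' at one pixel so that very narrow scales (e.g. `s = 0.1`) still span a
#' 3-pixel cross-section instead of collapsing to a single column that the
#' mean subtraction would annihilate. Each rotated support is sampled by
#' inverse-mapping integer offsets into the canonical frame (no holes), and
#' the support mean is subtracted so every kernel is exactly zero-mean.
#'
#' @param l template length in pixels.
#' @param s Gaussian width in pixels.
#' @param nDirs number of orientations (>= 1).
#' @param supersample odd subsample grid side per pixel for anti-aliased
#'   template rendering (default 5); 1 reverts to point sampling.
#' @details Each pixel's template value is the average of the continuous
#'   template over a `supersample x supersample` subgrid of the pixel
#'   (anti-aliasing): point sampling leaves narrow rotated templates with
#'   ragged, orientation-dependent supports whose responses are not
#'   comparable across angles. The Gaussian evaluation width is likewise
#'   clamped below at 1/3 px — a sub-pixel cross-section renders as a
#'   one-pixel-wide line — and, after mean subtraction, every kernel is
#'   scaled to unit energy so the pixelwise maximum over orientations
#'   compares like with like. None of this changes the downstream maps:
#'   responses are min-max rescaled before use.
#' @return a [KernelBank-class].
#' @examples
#' bank <- buildKernelBank(10.8, 1.9, 8)
#' sapply(bankKernels(bank), sum)  # all ~0
#' @export
buildKernelBank <- function(l, s, nDirs, supersample = 5) {
  if (!all(is.finite(c(l, s))) || l <= 0 || s <= 0)
    stop("l and s must be finite and positive")
  nDirs <- as.integer(nDirs)
  if (is.na(nDirs) || nDirs < 1) stop("nDirs must be >= 1")
  uMax <- max(3 * s, 1)
  if (3 * s < 1)
    message("matched-filter cross-section floored at 1 px (3s = ", 3 * s, ")")
  sEff <- max(s, 1 / 3)
  vMax <- l / 2
  half <- ceiling(sqrt(uMax^2 + vMax^2)) + 1L
  side <- 2L * half + 1L
  offs <- seq(-half, half)
  ss <- max(1L, as.integer(supersample))
  sub <- seq(-0.5 + 1 / (2 * ss), 0.5 - 1 / (2 * ss), length.out = ss)
  angles <- (seq_len(nDirs) - 1) * pi / nDirs
  kernels <- vector("list", nDirs)
  supports <- vector("list", nDirs)
  means <- numeric(nDirs)
  areas <- integer(nDirs)
  for (i in seq_len(nDirs)) {
    th <- angles[i]
    k <- matrix(0, side, side)
    hit <- matrix(FALSE, side, side)
    for (dx in sub) for (dy in sub) {
      # (x, y) image offsets: x along columns, y along rows; inverse-rotate
      # each subsample into the canonical (u, v) frame
      X <- matrix(rep(offs + dx, each = side), side, side)
      Y <- matrix(rep(offs + dy, times = side), side, side)
      u <- cos(th) * X + sin(th) * Y
      v <- -sin(th) * X + cos(th) * Y
      inside <- abs(u) <= uMax & abs(v) <= vMax
      k[inside] <- k[inside] - exp(-u[inside]^2 / (2 * sEff^2))
      hit <- hit | inside
    }
    k <- k / (ss * ss)
    m <- sum(k) / sum(hit)
    k[hit] <- k[hit] - m
    k <- k / sqrt(sum(k^2))
    kernels[[i]] <- k
    supports[[i]] <- hit
    means[i] <- m
    areas[i] <- sum(hit)
  }
  new("KernelBank", scale = s, len = l, nDirs = nDirs, angles = angles,
      kernels = kernels, supports = supports, means = means, areas = areas)
}

# Correlate one template with the image under reflect borders.
correlateKernel <- function(g, k) {
  half <- (nrow(k) - 1L) / 2L
  p <- padReflect(g, half)
  r <- EBImage::filter2(EBImage::Image(t(p)), t(k), boundary = "replicate")
  r <- t(as.matrix(EBImage::imageData(r)))
  r[(half + 1L):(half + nrow(g)), (half + 1L):(half + ncol(g)), drop = FALSE]
}

#' Matched-filter response
#'
#' Correlates the image with every rotated template of the bank (reflect
#' border handling) and keeps, per pixel, the maximum response over
#' orientations, then min-max rescales to `[0, 255]`. Dark line structure at
#' any bank orientation maps to a bright response.
#'
#' @param g grayscale matrix on 0-255 (dark vessels on bright background).
#' @param bank a [KernelBank-class].
#' @param rescale rescale the pooled response to 0-255 (default) or return
#'   the raw maximum response.
#' @param returnIndex also return the winning orientation index per pixel.
#' @return matrix (response), or a list `response`/`direction` when
#'   `returnIndex = TRUE`.
#' @export
matchedFilterResponse <- function(g, bank, rescale = TRUE, returnIndex = FALSE) {
  stopifnotMatrix(g)
  side <- nrow(bank@kernels[[1]])
  if (nrow(g) <= side || ncol(g) <= side)
    stop("image must be larger than the kernel support (", side, " px)")
  best <- NULL
  idx <- NULL
  for (i in seq_len(bank@nDirs)) {
    r <- correlateKernel(g, bank@kernels[[i]])
    if (is.null(best)) {
      best <- r
      if (returnIndex) idx <- matrix(1L, nrow(g), ncol(g))
    } else {
      if (returnIndex) idx[r > best] <- i
      best <- pmax(best, r)
    }
  }
  out <- if (rescale) rescale255(best, warnConstant = FALSE) else best
  if (returnIndex) list(response = out, direction = idx) else out
}

#' Black-hat configuration
#' @param radius structuring-element disc radius in pixels (>= 1).
#' @return list of class `blackHatConfig`.
#' @export
blackHatConfig <- function(radius = 11) {
  if (radius < 1) stop("structuring-element radius must be >= 1")
  structure(list(radius = radius), class = "blackHatConfig")
}

#' Inverted double black-hat transform
#'
#' `B_hat = closing(f) - f` (the classical black-hat, highlighting dark
#' detail smaller than the disc) followed by `g = 255 - (f - 2 * B_hat)`,
#' clipped to `[0, 255]`. Relative to a plain inversion this pushes the
#' black-hat detail twice as far, deepening vessel/background separation in
#' the inverted output.
#'
#' @param f grayscale matrix on 0-255.
#' @param cfg a [blackHatConfig()].
#' @return matrix on 0-255.
#' @export
blackHat2 <- function(f, cfg = blackHatConfig()) {
  stopifnotMatrix(f)
  bhat <- closeDisc(f, cfg$radius) - f
  clip255(255 - (f - 2 * bhat))
}

#' Channel specification
#'
#' Channel 1: closing-based background removal (disc radius 11). Channel 2:
#' large-scale bank (`l = 10.8`, `s = 1.9`, 8 orientations) + black hat.
#' Channel 3: small-scale bank (`l = 5`, `s = 0.1`, 18 orientations) +
#' black hat.
#'
#' @param channel channel id, 1, 2 or 3.
#' @param l,s,nDirs matched-filter parameters (channels 2/3); defaults are
#'   the published per-channel settings.
#' @param closeRadius closing / black-hat disc radius.
#' @return list of class `channelSpec`.
#' @export
channelSpec <- function(channel, l = NULL, s = NULL, nDirs = NULL,
                        closeRadius = 11) {
  channel <- as.integer(channel)
  if (!channel %in% 1:3) stop("unknown channel id: ", channel)
  if (channel == 2) {
    l <- l %||% 10.8; s <- s %||% 1.9; nDirs <- nDirs %||% 8L
  } else if (channel == 3) {
    l <- l %||% 5; s <- s %||% 0.1; nDirs <- nDirs %||% 18L
  }
  structure(list(channel = channel, l = l, s = s, nDirs = nDirs,
                 closeRadius = closeRadius), class = "channelSpec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one enhancement channel
#'
#' Applies the channel-specific enhancement to a preprocessed grayscale
#' image: channel 1 is [removeBackgroundClose()]; channels 2 and 3 are
#' [matchedFilterResponse()] with their scale's bank followed by
#' [blackHat2()].
#'
#' @param gPre preprocessed grayscale matrix on 0-255.
#' @param spec a [channelSpec()].
#' @return enhanced grayscale matrix on 0-255.
#' @export
enhanceChannel <- function(gPre, spec) {
  if (!inherits(spec, "channelSpec")) stop("spec must be a channelSpec")
  if (spec$channel == 1) {
    removeBackgroundClose(gPre, spec$closeRadius)
  } else {
    bank <- buildKernelBank(spec$l, spec$s, spec$nDirs)
    resp <- matchedFilterResponse(gPre, bank)
    blackHat2(resp, blackHatConfig(spec$closeRadius))
  }
}
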