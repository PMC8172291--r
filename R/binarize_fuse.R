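# Binarization of channel probability maps with a local-mean adaptive
# threshold, OR fusion of the three channel masks, and pruning of small
# 8-connected components.

#' Adaptive threshold configuration
#'
#' The local threshold at a pixel is `T = -b + localMean`, the mean taken
#' over a `(2*wm+1) x (2*wn+1)` window (reflect borders); a pixel is
#' foreground iff its value exceeds `T`. With the default `b = -15` the
#' threshold sits 15 gray levels above the local mean, so flat background
#' (probability ~0 everywhere in the window) stays background while locally
#' bright vessel ridges cross it. A positive `b` lowers the threshold below
#' the local mean, which marks every pixel of a constant region as
#' foreground — useful only for already high-contrast inputs.
#'
#' @param b fixed offset on the 0-255 scale (default -15).
#' @param window integer vector `c(wm, wn)` of window half-sizes (>= 1 each,
#'   giving an odd window of at least 3x3).
#' @return list of class `thresholdConfig`.
#' @export
thresholdConfig <- function(b = -15, window = c(15, 15)) {
  window <- rep_len(as.integer(window), 2L)
  if (any(window < 1)) stop("window half-sizes must be >= 1 (window >= 3x3)")
  structure(list(b = b, window = window), class = "thresholdConfig")
}

#' Local-mean adaptive threshold
#'
#' Binarizes a grayscale map (0-255 scale; probability maps are multiplied
#' by 255 beforehand) against `T = -b + localMean`; see
#' [thresholdConfig()].
#'
#' @param g grayscale matrix on 0-255.
#' @param cfg a [thresholdConfig()].
#' @return logical matrix.
#' @export
adaptiveThreshold <- function(g, cfg = thresholdConfig()) {
  stopifnotMatrix(g)
  wm <- cfg$window[1]; wn <- cfg$window[2]
  if (2 * wm + 1 > nrow(g) || 2 * wn + 1 > ncol(g))
    stop("threshold window larger than the image")
  p <- padReflect(g, c(wm, wn))
  box <- matrix(1 / ((2 * wm + 1) * (2 * wn + 1)), 2 * wm + 1, 2 * wn + 1)
  mu <- EBImage::filter2(EBImage::Image(t(p)), t(box), boundary = "replicate")
  mu <- t(as.matrix(EBImage::imageData(mu)))
  mu <- mu[(wm + 1):(wm + nrow(g)), (wn + 1):(wn + ncol(g)), drop = FALSE]
  g > (-cfg$b + mu)
}

#' OR fusion of channel masks
#'
#' Pixelwise logical OR: a pixel is vessel if any channel calls it vessel,
#' which is what reconnects fragments that individual channels break.
#'
#' @param m1,m2,m3 logical matrices of identical dims (`m3` optional).
#' @return logical matrix.
#' @export
fuseOr <- function(m1, m2, m3 = NULL) {
  sameDims(m1, m2, "masks")
  out <- m1 | m2
  if (!is.null(m3)) {
    sameDims(m1, m3, "masks")
    out <- out | m3
  }
  out
}

#' Remove small connected components
#'
#' Drops every 8-connected foreground component with strictly fewer than
#' `minSize` pixels (a 25-pixel component survives the default). Idempotent;
#' never adds pixels.
#'
#' @param mask logical matrix.
#' @param minSize minimum surviving component size in pixels (default 25).
#' @return logical matrix.
#' @export
removeSmallComponents <- function(mask, minSize = 25) {
  stopifnotMatrix(mask, "mask")
  if (!any(mask)) return(mask)
  lab <- labelComponents(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minSize)
  matrix(lab %in% keep, nrow(lab), ncol(lab)) & mask
}

#' End-to-end segmentation of one fundus image
#'
#' Full pipeline: preprocessing, the three enhancement channels, per-channel
#' network prediction in the square frame, adaptive-threshold binarization,
#' OR fusion, restoration to native dimensions, FOV masking, and small-
#' component pruning (applied at native scale). Deterministic.
#'
#' @param img H x W x 3 fundus array on 0-255.
#' @param models list of three trained [UNetModel-class] objects (channels
#'   1, 2, 3 in order).
#' @param preCfg a [preprocessConfig()].
#' @param channelSpecs list of three [channelSpec()]s.
#' @param thrCfg a [thresholdConfig()].
#' @param minSize pruning threshold in pixels.
#' @param side network frame side; defaults to the first model's spec.
#' @param fov optional logical FOV mask (native dims); pixels outside are
#'   forced to background after fusion.
#' @param detail also return per-channel masks and probability maps.
#' @return logical mask at native dims; with `detail = TRUE`, a list with
#'   `mask`, `channels` (three native-dim masks) and `probs`.
#' @export
segmentFundus <- function(img, models, preCfg = preprocessConfig(),
                          channelSpecs = lapply(1:3, channelSpec),
                          thrCfg = thresholdConfig(), minSize = 25,
                          side = NULL, fov = NULL, detail = FALSE) {
  if (length(models) != 3) stop("need three channel models (missing checkpoint?)")
  side <- side %||% models[[1]]@spec$side
  gPre <- preprocessFundus(img, preCfg)
  origDim <- dim(gPre)
  chanMasks <- vector("list", 3)
  probs <- vector("list", 3)
  frameMasks <- vector("list", 3)
  for (k in 1:3) {
    enh <- enhanceChannel(gPre, channelSpecs[[k]])
    fr <- toNetworkFrame(enh, side)
    pm <- predictChannel(models[[k]], fr)
    probs[[k]] <- pm
    frameMasks[[k]] <- adaptiveThreshold(pm * 255, thrCfg)
    chanMasks[[k]] <- fromNetworkFrame(frameMasks[[k]], origDim, binary = TRUE)
  }
  fusedFrame <- fuseOr(frameMasks[[1]], frameMasks[[2]], frameMasks[[3]])
  fused <- fromNetworkFrame(fusedFrame, origDim, binary = TRUE)
  if (!is.null(fov)) {
    sameDims(fused, fov, "mask and FOV")
    fused <- fused & fov
    chanMasks <- lapply(chanMasks, function(m) m & fov)
  }
  out <- removeSmallComponents(fused, minSize)
  if (detail) list(mask = out, channels = chanMasks, probs = probs) else out
}
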