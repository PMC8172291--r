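#' @import methods
NULL

#' Rotated matched-filter kernel bank
#'
#' A set of rotated, mean-subtracted Gaussian line templates. The canonical
#' (unrotated) template is an inverted Gaussian ridge: intensity
#' `-exp(-u^2 / (2 s^2))` across the vessel (coordinate `u`), constant along
#' it (coordinate `v`), restricted to `|u| <= max(3 s, 1)` and `|v| <= l / 2`.
#' Each orientation is sampled by mapping every integer offset of a common
#' bounding square back into the canonical frame with the inverse rotation,
#' so rotated supports have no holes. The per-orientation mean over the
#' support is subtracted, making every kernel zero-mean, which yields zero
#' response on locally constant background.
#'
#' @slot scale Gaussian width `s` in pixels.
#' @slot len template length `l` in pixels.
#' @slot nDirs number of orientations.
#' @slot angles orientation angles, `(i-1) * pi / nDirs`.
#' @slot kernels list of square numeric templates (zeros outside support).
#' @slot supports list of logical matrices marking each template's support.
#' @slot means subtracted per-orientation means.
#' @slot areas per-orientation support point counts.
#' @export
setClass("KernelBank",
  representation(
    scale = "numeric", len = "numeric", nDirs = "integer",
    angles = "numeric", kernels = "list", supports = "list",
    means = "numeric", areas = "integer"
  )
)

setValidity("KernelBank", function(object) {
  msgs <- character()
  n <- object@nDirs
  if (length(object@kernels) != n) msgs <- c(msgs, "need exactly nDirs kernels")
  if (length(object@angles) != n) msgs <- c(msgs, "need exactly nDirs angles")
  relSums <- vapply(object@kernels, function(k) {
    tot <- sum(abs(k)); if (tot == 0) 1 else abs(sum(k)) / tot
  }, numeric(1))
  if (any(relSums >= 1e-9))
    msgs <- c(msgs, "kernels must be zero-mean (relative |sum| < 1e-9)")
  if (length(msgs)) msgs else TRUE
})

#' Encoder-decoder segmentation model
#'
#' Container for the fully convolutional encoder-decoder: the architecture
#' description (`spec`), the learnable arrays (`params`), and the batch-norm
#' running statistics (`buffers`). Build with [buildUNet()]; inspect the
#' learnable-term ledger with [countParameters()].
#'
#' @slot spec list describing widths and wiring, from [unetSpec()].
#' @slot params named list of learnable arrays, one entry per block.
#' @slot buffers named list of batch-norm running means/variances.
#' @slot seed integer seed the initial weights were drawn from.
#' @export
setClass("UNetModel",
  representation(spec = "list", params = "list", buffers = "list",
                 seed = "integer")
)

setValidity("UNetModel", function(object) {
  if (length(object@params) == 0) return("model has no parameters")
  vals <- unlist(object@params, recursive = TRUE, use.names = FALSE)
  if (!all(is.finite(vals))) return("non-finite parameter values")
  TRUE
})

#' Synthetic fundus phantom
#'
#' A generated fundus-like scene: bright background with a smooth
#' illumination gradient and optional optic-disc blob, dark curvilinear
#' vessels with an inverted-Gaussian cross-section, a circular field of view,
#' additive noise, plus exact vessel ground truth derived from the analytic
#' distance to each centerline (not re-thresholded from the rendering).
#'
#' @slot image H x W x 3 integer-valued array on 0-255 (RGB planes; green
#'   carries the strongest vessel contrast).
#' @slot gt logical matrix, vessel ground truth.
#' @slot fov logical matrix, circular field-of-view aperture.
#' @slot config generator configuration, from [phantomConfig()].
#' @slot seed seed that reproduces the triple bit-for-bit.
#' @export
setClass("Phantom",
  representation(image = "array", gt = "matrix", fov = "matrix",
                 config = "list", seed = "integer")
)

setValidity("Phantom", function(object) {
  d <- dim(object@image)
  if (length(d) != 3 || d[3] != 3) return("image must be H x W x 3")
  if (min(object@image) < 0 || max(object@image) > 255)
    return("image values must lie in [0,255]")
  if (!is.logical(object@gt) || !is.logical(object@fov))
    return("gt and fov must be logical matrices")
  if (!identical(dim(object@gt), d[1:2]) || !identical(dim(object@fov), d[1:2]))
    return("gt/fov dimensions must match the image")
  if (any(object@gt & !object@fov)) return("ground truth must lie inside the FOV")
  TRUE
})

#' @describeIn KernelBank-class brief summary of the bank.
#' @param object a `KernelBank`.
#' @export
setMethod("show", "KernelBank", function(object) {
  cat(sprintf("KernelBank: l = %g, s = %g, %d orientations (side %d)\n",
              object@len, object@scale, object@nDirs, nrow(object@kernels[[1]])))
  cat(sprintf("  angles: %s deg\n",
              paste(round(object@angles * 180 / pi, 1), collapse = ", ")))
  invisible(NULL)
})

#' @describeIn UNetModel-class prints the architecture and total learnable terms.
#' @param object a `UNetModel`.
#' @export
setMethod("show", "UNetModel", function(object) {
  s <- object@spec
  cat(sprintf("UNetModel: encoder %s | decoder %s | input side %d\n",
              paste(s$encoder, collapse = "-"),
              paste(s$decoder, collapse = "-"), s$side))
  cat(sprintf("  learnable terms: %s (seed %d)\n",
              format(nParams(object), big.mark = ","), object@seed))
  invisible(NULL)
})

#' @describeIn Phantom-class prints frame size and vessel prevalence.
#' @param object a `Phantom`.
#' @export
setMethod("show", "Phantom", function(object) {
  prev <- 100 * sum(object@gt) / max(1, sum(object@fov))
  cat(sprintf("Phantom: %d x %d, %d vessel px (%.1f%% of FOV), seed %d\n",
              nrow(object@gt), ncol(object@gt), sum(object@gt), prev,
              object@seed))
  invisible(NULL)
})
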