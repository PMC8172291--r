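# Shared low-level helpers: padding, disc structuring elements, rescaling.
# Image convention throughout: numeric matrix, rows = image rows (y), columns =
# image columns (x), intensities on the 0-255 scale; masks are logical matrices.

#' Reflect-pad a matrix
#'
#' Pads a matrix by mirror reflection (edge row/column not repeated), the
#' border rule used by every windowed operation in the package (correlation,
#' morphology, local-mean thresholding).
#'
#' @param m numeric matrix.
#' @param margin integer vector of length 1 or 2, pad widths for rows/cols.
#' @return padded matrix of size `(nrow + 2*margin[1]) x (ncol + 2*margin[2])`.
#' @keywords internal
padReflect <- function(m, margin) {
  margin <- rep_len(as.integer(margin), 2L)
  h <- nrow(m); w <- ncol(m)
  if (margin[1] >= h || margin[2] >= w)
    stop("reflect pad margin must be smaller than the image")
  ri <- c(rev(seq_len(margin[1]) + 1L), seq_len(h), h - seq_len(margin[1]))
  ci <- c(rev(seq_len(margin[2]) + 1L), seq_len(w), w - seq_len(margin[2]))
  m[ri, ci, drop = FALSE]
}

#' Euclidean disc structuring element
#'
#' 0/1 matrix of side `2*radius + 1` containing the integer offsets with
#' `dx^2 + dy^2 <= radius^2`.
#'
#' @param radius disc radius in pixels, `>= 1`.
#' @return numeric 0/1 matrix.
#' @export
discKernel <- function(radius) {
  radius <- as.numeric(radius)
  if (!is.finite(radius) || radius < 1) stop("disc radius must be >= 1")
  r <- floor(radius)
  d <- seq(-r, r)
  k <- outer(d, d, function(y, x) as.numeric(x^2 + y^2 <= radius^2))
  k
}

# Min-max rescale to [0, 255]; a constant input triggers the degenerate path:
# all-zero output plus a warning (callers rely on this contract).
rescale255 <- function(m, warnConstant = TRUE) {
  lo <- min(m); hi <- max(m)
  if (!is.finite(lo) || !is.finite(hi)) stop("non-finite values in image")
  if (hi == lo) {
    if (warnConstant) warning("degenerate input: constant image, returning zeros")
    return(array(0, dim(m)))
  }
  (m - lo) / (hi - lo) * 255
}

clip255 <- function(m) pmin(pmax(m, 0), 255)

# Grayscale closing with an exact-Euclidean disc and reflect borders.
# EBImage performs the min/max filtering on the [0,1] scale it expects
# (its grayscale erosion saturates at 1); the reflect pad keeps its border
# handling away from the region of interest.
closeDisc <- function(m, radius) {
  k <- discKernel(radius)
  r <- (nrow(k) - 1L) / 2L
  p <- padReflect(m, r) / 255
  cl <- EBImage::closing(p, k)
  cl <- as.matrix(EBImage::imageData(cl)) * 255
  cl[(r + 1L):(r + nrow(m)), (r + 1L):(r + ncol(m)), drop = FALSE]
}

# Binary dilation by an exact-Euclidean disc (logical in, logical out).
dilateDisc <- function(mask, radius) {
  k <- discKernel(radius)
  d <- EBImage::dilate(mask * 1, k)
  as.matrix(EBImage::imageData(d)) > 0.5
}

# 8-connected component labelling (compiled union-find; diagonal contact
# joins components, the adjacency used throughout the pipeline).
labelComponents <- function(mask) {
  if (!is.logical(mask)) mask <- mask > 0.5
  .label8(mask)
}

stopifnotMatrix <- function(m, what = "image") {
  if (!is.matrix(m)) stop(what, " must be a matrix")
  invisible(m)
}

sameDims <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) stop(what, " must share dimensions")
  invisible(TRUE)
}

# Deterministic per-stage seed fan-out: one user seed expands to independent
# stage seeds below 2^31.
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 1000000L) * 2017L + (h %% 99991L)
}
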