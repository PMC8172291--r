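# Image and mask I/O, color-channel extraction, FOV mask construction,
# dataset split definitions, and mapping to/from the square network frame.
#
# Conventions: fundus images are H x W x 3 arrays of integers on 0-255;
# grayscale images are numeric matrices on 0-255; masks are logical matrices
# in memory and 0/255 single-channel PNG on disk. Indexing is row-major
# (row, col).

#' Read a fundus image
#'
#' Decodes an 8-bit RGB or grayscale image (PNG/TIFF/JPEG/GIF/PPM); a
#' grayscale source is replicated onto all three planes.
#'
#' @param path file path.
#' @return H x W x 3 numeric array with values in `[0, 255]`.
#' @examples
#' p <- generatePhantom(phantomConfig(side = 64), seed = 1)
#' f <- tempfile(fileext = ".png")
#' writeFundus(phantomImage(p), f)
#' img <- readFundus(f)
#' @export
readFundus <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode image ", path, ": ",
                                           conditionMessage(e)))
  a <- EBImage::imageData(img)
  # EBImage stores (x, y[, c]) on [0,1]; transpose to (row, col).
  if (length(dim(a)) == 2) {
    m <- t(a)
    out <- array(rep(m, 3), c(dim(m), 3))
  } else {
    nc <- dim(a)[3]
    if (nc < 3) {
      m <- t(a[, , 1])
      out <- array(rep(m, 3), c(dim(m), 3))
    } else {
      out <- array(0, c(dim(a)[2], dim(a)[1], 3))
      for (k in 1:3) out[, , k] <- t(a[, , k])
    }
  }
  out <- round(out * 255)
  if (min(out) < 0 || max(out) > 255)
    stop("unsupported bit depth in ", path, ": values outside [0,255]")
  out
}

#' Write a fundus image as 8-bit PNG/TIFF/JPEG
#' @param img H x W x 3 array on 0-255 (or H x W matrix).
#' @param path output path; format from the extension.
#' @return the path, invisibly.
#' @export
writeFundus <- function(img, path) {
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
  a <- array(0, c(dim(img)[2], dim(img)[1], 3))
  for (k in 1:3) a[, , k] <- t(img[, , k]) / 255
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

#' Read / write binary masks
#'
#' Masks are stored as single-channel PNG with 0 background and 255
#' foreground; any strictly positive gray value reads back as foreground.
#'
#' @param mask logical matrix.
#' @param path file path.
#' @return `readMask()`: logical matrix; `writeMask()`: the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnotMatrix(mask, "mask")
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: file not found: ", path)
  a <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(a)) == 3) a <- a[, , 1]
  t(a) > 0.5
}

#' Extract the green channel
#'
#' Retinal vessels show the strongest vessel/background contrast on the
#' green plane, which is the input to all downstream preprocessing.
#'
#' @param img H x W x 3 fundus array.
#' @return numeric matrix on 0-255.
#' @export
extractGreen <- function(img) {
  if (length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("expected an H x W x 3 fundus image")
  img[, , 2]
}

#' Build a field-of-view mask
#'
#' Recovers the circular camera aperture from the dark frame border: green
#' plane, Gaussian blur, Otsu threshold, hole filling, largest 8-connected
#' component, then binary erosion by a disc to pull the boundary inward.
#'
#' @param img H x W x 3 fundus array.
#' @param blurSigma Gaussian blur sigma in pixels.
#' @param erodeRadius boundary erosion margin in pixels.
#' @return logical matrix.
#' @export
makeFovMask <- function(img, blurSigma = 3, erodeRadius = 3) {
  g <- extractGreen(img) / 255
  gb <- as.matrix(EBImage::imageData(EBImage::gblur(g, sigma = blurSigma)))
  thr <- EBImage::otsu(EBImage::Image(gb), range = c(0, 1))
  bw <- gb > thr
  if (!any(bw)) stop("empty FOV mask: no pixel exceeds the threshold")
  bw <- as.matrix(EBImage::imageData(EBImage::fillHull(bw * 1))) > 0.5
  lab <- labelComponents(bw)
  sizes <- tabulate(lab[lab > 0])
  bw <- lab == which.max(sizes)
  if (erodeRadius >= 1) {
    k <- discKernel(erodeRadius)
    bw <- as.matrix(EBImage::imageData(EBImage::erode(bw * 1, k))) > 0.5
  }
  if (!any(bw)) stop("empty FOV mask: erosion removed all foreground")
  bw
}

#' Map a grayscale image to and from the square network frame
#'
#' The network consumes square frames whose side is divisible by 16 (576 for
#' full-resolution work). `toNetworkFrame()` resizes bilinearly and records
#' the original dimensions; `fromNetworkFrame()` restores them — bilinearly
#' for continuous maps, nearest-neighbor for masks so binarized predictions
#' stay two-valued.
#'
#' @param g numeric matrix (or logical matrix for the backward mapping).
#' @param side target frame side, default 576.
#' @param origDim integer vector `c(rows, cols)` to restore.
#' @param binary logical; use nearest-neighbor restoration for masks.
#' @return matrix; `toNetworkFrame()` attaches the original dims as
#'   attribute `origDim`.
#' @export
toNetworkFrame <- function(g, side = 576) {
  stopifnotMatrix(g)
  if (nrow(g) < 1 || ncol(g) < 1) stop("non-positive image dimensions")
  d <- dim(g)
  out <- if (all(d == side)) g else resizeBilinear(g, side, side)
  attr(out, "origDim") <- d
  out
}

#' @rdname toNetworkFrame
#' @export
fromNetworkFrame <- function(g, origDim, binary = FALSE) {
  origDim <- as.integer(origDim)
  if (any(origDim < 1)) stop("non-positive target dimensions")
  if (all(dim(g) == origDim)) {
    out <- g
  } else if (binary) {
    out <- resizeNearest(g * 1, origDim[1], origDim[2]) > 0.5
  } else {
    out <- resizeBilinear(g, origDim[1], origDim[2])
  }
  attr(out, "origDim") <- NULL
  out
}

resizeBilinear <- function(m, h, w) {
  r <- EBImage::resize(EBImage::Image(t(m)), w = w, h = h)
  t(as.matrix(EBImage::imageData(r)))
}

resizeNearest <- function(m, h, w) {
  ri <- pmin(nrow(m), pmax(1L, as.integer(floor((seq_len(h) - 0.5) *
                                                nrow(m) / h) + 1L)))
  ci <- pmin(ncol(m), pmax(1L, as.integer(floor((seq_len(w) - 0.5) *
                                                ncol(m) / w) + 1L)))
  m[ri, ci, drop = FALSE]
}

#' Published dataset train/test splits
#'
#' Returns the conventional splits of the three public fundus benchmarks:
#' DRIVE's published 20/20 split, the 5-image STARE test set (im0002,
#' im0077, im0163, im0255, im0291) with the remaining 15 for training, and
#' CHASE_DB1 with the first 20 images for training and the last 8 for test.
#'
#' @param dataset one of `"DRIVE"`, `"STARE"`, `"CHASE_DB1"`.
#' @return list with `dataset`, `train`, `test` (character id vectors).
#' @examples
#' datasetSplit("STARE")$test
#' @export
datasetSplit <- function(dataset = c("DRIVE", "STARE", "CHASE_DB1")) {
  dataset <- match.arg(dataset)
  if (dataset == "DRIVE") {
    train <- sprintf("%02d_training", 21:40)
    test <- sprintf("%02d_test", 1:20)
  } else if (dataset == "STARE") {
    all <- c("im0001", "im0002", "im0003", "im0004", "im0005", "im0044",
             "im0077", "im0081", "im0082", "im0139", "im0162", "im0163",
             "im0235", "im0236", "im0239", "im0240", "im0255", "im0291",
             "im0319", "im0324")
    test <- c("im0002", "im0077", "im0163", "im0255", "im0291")
    train <- setdiff(all, test)
  } else {
    ids <- paste0("Image_", rep(sprintf("%02d", 1:14), each = 2), c("L", "R"))
    train <- ids[1:20]
    test <- ids[21:28]
  }
  stopifnot(length(intersect(train, test)) == 0)
  list(dataset = dataset, train = train, test = test)
}

#' Read / write a dataset manifest
#'
#' A manifest is a YAML file listing, per split, the image / label / FOV
#' paths of each item; it is the hand-off format between the phantom
#' generator, the training loop, and the evaluator.
#'
#' @param manifest list with elements `name` and `items` (a data.frame with
#'   columns `id`, `split`, `image`, `label`, `fov`).
#' @param path YAML file path.
#' @return `readManifest()`: the manifest list.
#' @export
writeManifest <- function(manifest, path) {
  items <- manifest$items
  yaml::write_yaml(list(name = manifest$name,
                        items = lapply(seq_len(nrow(items)), function(i)
                          as.list(items[i, , drop = FALSE]))), path)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  y <- yaml::read_yaml(path)
  items <- do.call(rbind, lapply(y$items, function(it)
    as.data.frame(it, stringsAsFactors = FALSE)))
  list(name = y$name, items = items)
}
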