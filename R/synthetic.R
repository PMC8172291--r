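# Seed-reproducible fundus phantoms: a bright background with a smooth
# illumination field and an optional optic-disc blob, dark curvilinear
# vessels with an inverted-Gaussian cross-section, a circular field of
# view, and additive Gaussian noise. Ground truth comes from the analytic
# distance to each vessel centerline, so labels are exact rather than
# re-thresholded from the rendering.

#' Phantom generator configuration
#'
#' Defaults emulate the statistics the pipeline is designed around: a ~200
#' gray-level background, vessels 1-6 px wide with center-line dips of
#' 40-80 gray levels, a circular FOV of 0.48 of the frame side, noise sigma
#' 5, and a vessel prevalence of a few percent of the FOV.
#'
#' @param side frame side in pixels (default 256).
#' @param nVessels number of vessels drawn from the disc center outwards.
#' @param widthRange vessel full widths in pixels, `c(min, max)`.
#' @param depthRange centerline intensity dip on 0-255, `c(min, max)`.
#' @param background base background intensity.
#' @param illumAmplitude amplitude of the smooth illumination gradient.
#' @param noiseSigma additive Gaussian noise sigma.
#' @param fovFraction FOV radius as a fraction of the side.
#' @param opticDisc draw a bright disc-like blob near the vessel origin.
#' @return list of class `phantomConfig`.
#' @export
phantomConfig <- function(side = 256, nVessels = 8, widthRange = c(1, 6),
                          depthRange = c(40, 80), background = 200,
                          illumAmplitude = 15, noiseSigma = 5,
                          fovFraction = 0.48, opticDisc = TRUE) {
  if (widthRange[1] < 1) stop("vessel widths must be >= 1 px")
  if (max(depthRange) >= background)
    stop("vessel dip depth must stay below the background level")
  if (side < 8 * widthRange[2]) stop("frame too small for requested widths")
  structure(list(side = as.integer(side), nVessels = as.integer(nVessels),
                 widthRange = widthRange, depthRange = depthRange,
                 background = background, illumAmplitude = illumAmplitude,
                 noiseSigma = noiseSigma, fovFraction = fovFraction,
                 opticDisc = isTRUE(opticDisc)), class = "phantomConfig")
}

# Quadratic Bezier curve through p0 with control p1 and endpoint p2,
# sampled densely; bounded curvature comes from a bounded control offset.
bezierPoints <- function(p0, p1, p2, n = 200) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

# Exact distance from every pixel in a bounding box to a polyline.
polylineDistance <- function(side, pts, maxDist) {
  lo <- pmax(1, floor(apply(pts, 2, min)) - ceiling(maxDist))
  hi <- pmin(side, ceiling(apply(pts, 2, max)) + ceiling(maxDist))
  if (any(lo > hi)) return(NULL)
  rows <- lo[1]:hi[1]; cols <- lo[2]:hi[2]
  py <- rep(rows, times = length(cols))
  px <- rep(cols, each = length(rows))
  d2 <- rep(Inf, length(py))
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  for (s in seq_len(nrow(a))) {
    vy <- py - a[s, 1]; vx <- px - a[s, 2]
    t <- if (len2[s] > 0) pmin(1, pmax(0, (vy * ab[s, 1] + vx * ab[s, 2]) /
                                            len2[s])) else 0
    dy <- vy - t * ab[s, 1]; dx <- vx - t * ab[s, 2]
    d2 <- pmin(d2, dy * dy + dx * dx)
  }
  list(rows = rows, cols = cols,
       dist = matrix(sqrt(d2), length(rows), length(cols)))
}

#' Generate one fundus phantom
#'
#' Vessels start near the optic-disc location and follow random quadratic
#' curves of bounded curvature; the rendered intensity along a vessel is
#' `background - depth * exp(-d^2 / (2 * sigma_w^2))` with `d` the distance
#' to the centerline and `sigma_w = width / 2`. The ground truth marks
#' pixels within `width / 2` of a centerline (clipped to the FOV). The
#' green plane carries full vessel contrast; red and blue carry reduced
#' contrast at lower base intensity, as in real fundus photographs.
#'
#' @param cfg a [phantomConfig()].
#' @param seed integer seed; the triple is a pure function of (cfg, seed).
#' @return a [Phantom-class].
#' @examples
#' p <- generatePhantom(phantomConfig(side = 128), seed = 7)
#' p
#' @export
generatePhantom <- function(cfg = phantomConfig(), seed = 1L) {
  seed <- as.integer(seed)
  set.seed(seed)
  n <- cfg$side
  ctr <- (n + 1) / 2
  fovR <- cfg$fovFraction * n
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  rad <- sqrt((ys - ctr)^2 + (xs - ctr)^2)
  fov <- rad <= fovR

  # smooth illumination: tilted plane plus a broad radial term
  thIl <- stats::runif(1, 0, 2 * pi)
  illum <- cfg$illumAmplitude *
    (((xs - ctr) * cos(thIl) + (ys - ctr) * sin(thIl)) / n +
       0.5 * (1 - (rad / fovR)^2))
  scene <- cfg$background + illum

  # optic disc: bright blob offset from center; vessels originate near it
  discPos <- c(ctr + stats::runif(1, -0.15, 0.15) * n,
               ctr + sign(stats::runif(1) - 0.5) * stats::runif(1, 0.2, 0.3) * n)
  if (cfg$opticDisc) {
    dd2 <- (ys - discPos[1])^2 + (xs - discPos[2])^2
    scene <- scene + 30 * exp(-dd2 / (2 * (0.05 * n)^2))
  }

  gt <- matrix(FALSE, n, n)
  vessel <- matrix(0, n, n)  # accumulated dip depth
  widths <- stats::runif(cfg$nVessels, cfg$widthRange[1], cfg$widthRange[2])
  depths <- stats::runif(cfg$nVessels, cfg$depthRange[1], cfg$depthRange[2])
  for (v in seq_len(cfg$nVessels)) {
    th0 <- stats::runif(1, 0, 2 * pi)
    len <- stats::runif(1, 0.55, 0.95) * fovR
    p0 <- discPos + stats::runif(2, -0.03, 0.03) * n
    p2 <- p0 + len * c(sin(th0), cos(th0))
    mid <- (p0 + p2) / 2
    perp <- c(cos(th0), -sin(th0))
    p1 <- mid + stats::runif(1, -0.18, 0.18) * len * perp
    pts <- bezierPoints(p0, p1, p2)
    sw <- widths[v] / 2
    pd <- polylineDistance(n, pts, maxDist = 3 * sw + 2)
    if (is.null(pd)) next
    dip <- depths[v] * exp(-pd$dist^2 / (2 * sw^2))
    vessel[pd$rows, pd$cols] <- pmax(vessel[pd$rows, pd$cols], dip)
    gt[pd$rows, pd$cols] <- gt[pd$rows, pd$cols] | (pd$dist <= widths[v] / 2)
  }
  gt <- gt & fov

  green <- scene - vessel
  green[!fov] <- stats::runif(sum(!fov), 0, 12)
  green <- green + stats::rnorm(n * n, 0, cfg$noiseSigma)
  red <- 0.8 * scene - 0.4 * vessel
  red[!fov] <- stats::runif(sum(!fov), 0, 12)
  red <- red + stats::rnorm(n * n, 0, cfg$noiseSigma)
  blue <- 0.35 * scene - 0.15 * vessel
  blue[!fov] <- stats::runif(sum(!fov), 0, 10)
  blue <- blue + stats::rnorm(n * n, 0, cfg$noiseSigma)

  img <- array(0, c(n, n, 3))
  img[, , 1] <- red; img[, , 2] <- green; img[, , 3] <- blue
  img <- round(clip255(img))
  new("Phantom", image = img, gt = gt, fov = fov, config = unclass(cfg),
      seed = seed)
}

#' Generate a phantom suite with a manifest
#'
#' Produces `n` phantoms under per-item seeds derived from `seed`. With an
#' output directory the images and masks are written to disk (PNG) and the
#' manifest (readable by [readManifest()]) points at the files; otherwise
#' the phantoms are returned in memory.
#'
#' @param n number of phantoms (>= 1).
#' @param cfg a [phantomConfig()].
#' @param seed master seed; item `i` uses a seed derived from `(seed, i)`.
#' @param dir optional output directory.
#' @param trainFraction fraction of items tagged `train` in the manifest.
#' @return list with `phantoms` (list of [Phantom-class]; `NULL` entries
#'   when written to disk), `manifest`, and `dir`.
#' @export
generateSuite <- function(n, cfg = phantomConfig(), seed = 1L, dir = NULL,
                          trainFraction = 0.8) {
  if (n < 1) stop("need n >= 1 phantoms")
  seeds <- stageSeed(seed, "suite") + 7919L * seq_len(n)
  phantoms <- lapply(seeds, function(s) generatePhantom(cfg, seed = s))
  nTrain <- round(trainFraction * n)
  split <- rep(c("train", "test"), c(nTrain, n - nTrain))
  ids <- sprintf("phantom%03d", seq_len(n))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- lapply(seq_len(n), function(i) {
      img <- file.path(dir, paste0(ids[i], ".png"))
      lab <- file.path(dir, paste0(ids[i], "_gt.png"))
      fv <- file.path(dir, paste0(ids[i], "_fov.png"))
      writeFundus(phantomImage(phantoms[[i]]), img)
      writeMask(phantomTruth(phantoms[[i]]), lab)
      writeMask(phantomFov(phantoms[[i]]), fv)
      c(img, lab, fv)
    })
    items <- data.frame(id = ids, split = split,
                        image = vapply(paths, `[`, "", 1),
                        label = vapply(paths, `[`, "", 2),
                        fov = vapply(paths, `[`, "", 3),
                        stringsAsFactors = FALSE)
  } else {
    items <- data.frame(id = ids, split = split, image = NA, label = NA,
                        fov = NA, stringsAsFactors = FALSE)
  }
  manifest <- list(name = "phantom-suite", items = items)
  if (!is.null(dir)) writeManifest(manifest, file.path(dir, "manifest.yaml"))
  list(phantoms = phantoms, manifest = manifest, dir = dir)
}
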