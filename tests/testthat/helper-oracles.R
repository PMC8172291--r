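# Independent brute-force oracles used to check the package's windowed
# operations. All of them use explicit loops over pixel neighborhoods with
# mirror-reflected borders, sharing no code with the implementation paths
# (EBImage / compiled kernels).

# reflect an out-of-range 1-based index into [1, n] (edge not repeated)
reflectIndex <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 2 - i
    if (i > n) i <- 2 * n - i
  }
  i
}

# grayscale dilation/erosion by an arbitrary 0/1 kernel, reflect borders
bruteMorph <- function(m, kern, op = max) {
  r <- (nrow(kern) - 1) / 2
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    vals <- c()
    for (a in -r:r) for (b in -r:r) {
      if (kern[a + r + 1, b + r + 1] == 0) next
      vals <- c(vals, m[reflectIndex(i + a, nrow(m)),
                        reflectIndex(j + b, ncol(m))])
    }
    out[i, j] <- op(vals)
  }
  out
}

bruteClosing <- function(m, kern) bruteMorph(bruteMorph(m, kern, max), kern, min)

# direct correlation of an image with a centered kernel, reflect borders
bruteCorrelate <- function(m, k) {
  r <- (nrow(k) - 1) / 2
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    s <- 0
    for (a in -r:r) for (b in -r:r) {
      s <- s + k[a + r + 1, b + r + 1] *
        m[reflectIndex(i + a, nrow(m)), reflectIndex(j + b, ncol(m))]
    }
    out[i, j] <- s
  }
  out
}

# local window mean with reflect borders (for the adaptive threshold)
bruteLocalMean <- function(m, wm, wn) {
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    s <- 0
    for (a in -wm:wm) for (b in -wn:wn) {
      s <- s + m[reflectIndex(i + a, nrow(m)), reflectIndex(j + b, ncol(m))]
    }
    out[i, j] <- s / ((2 * wm + 1) * (2 * wn + 1))
  }
  out
}

# 8-connected component labelling by flood fill
bruteLabel <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (a in -1:1) for (b in -1:1) {
        ii <- p[1] + a; jj <- p[2] + b
        if (ii < 1 || jj < 1 || ii > nrow(mask) || jj > ncol(mask)) next
        if (mask[ii, jj] && lab[ii, jj] == 0) {
          lab[ii, jj] <- nxt
          queue <- c(queue, list(c(ii, jj)))
        }
      }
    }
  }
  lab
}

# rank AUC of scores against binary labels (used for the phantom
# separation property)
rankAuc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Dark line with an inverted-Gaussian cross-section through the center of a
# bright field, rendered from the analytic point-line distance (no aliasing).
# The angle follows the kernel-bank convention: theta = 0 runs along image
# rows (a vertical line), increasing theta rotates the line the same way the
# bank's templates rotate.
lineFixture <- function(side, theta, sigma = 1, depth = 120, bg = 200) {
  ctr <- (side + 1) / 2
  xs <- matrix(rep(seq_len(side), each = side), side, side)   # column
  ys <- matrix(rep(seq_len(side), times = side), side, side)  # row
  d <- abs((ys - ctr) * sin(theta) + (xs - ctr) * cos(theta))
  bg - depth * exp(-d^2 / (2 * sigma^2))
}

# winning orientation of a bank at the exact center of a line fixture
centerWinner <- function(bank, img, ctr = (nrow(img) + 1) / 2) {
  resp <- vapply(bankKernels(bank), function(k)
    VesselFuse:::correlateKernel(img, k)[ctr, ctr], numeric(1))
  which.max(resp)
}

circularStep <- function(a, b, n) {
  d <- abs(a - b)
  min(d, n - d)
}

smallPhantom <- function(seed = 5, side = 128) {
  generatePhantom(phantomConfig(side = side), seed = seed)
}

hardDiceOf <- function(pred, truth) {
  denom <- sum(pred) + sum(truth)
  if (denom == 0) return(1)
  2 * sum(pred & truth) / denom
}
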