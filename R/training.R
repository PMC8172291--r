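# Per-channel training: 4x geometric augmentation, SGD with momentum under
# the three-stage learning-rate schedule, per-epoch logging, and best-epoch
# model selection on a held-out validation Dice.

#' Four-fold geometric augmentation
#'
#' Expands each (image, label) pair into four: the original, a horizontal
#' flip, a vertical flip, and a 180-degree rotation, with the label (and any
#' extra mask) transformed jointly with the image.
#'
#' @param pairs list of lists with elements `image` (matrix) and `label`
#'   (matrix), plus any other matrix elements (e.g. `fov`), all sharing dims.
#' @return list of length `4 * length(pairs)`; each element gains a
#'   `provenance` tag in `original`, `hflip`, `vflip`, `rot180`.
#' @export
augment4x <- function(pairs) {
  flips <- list(
    original = identity,
    hflip = function(m) m[, rev(seq_len(ncol(m))), drop = FALSE],
    vflip = function(m) m[rev(seq_len(nrow(m))), , drop = FALSE],
    rot180 = function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))),
                           drop = FALSE]
  )
  out <- vector("list", 4L * length(pairs))
  j <- 0L
  for (pr in pairs) {
    if (!identical(dim(pr$image), dim(pr$label)))
      stop("image and label dimensions must match")
    for (tag in names(flips)) {
      f <- flips[[tag]]
      aug <- lapply(pr, function(el) if (is.matrix(el)) f(el) else el)
      aug$provenance <- tag
      j <- j + 1L
      out[[j]] <- aug
    }
  }
  out
}

#' Three-stage learning-rate schedule
#'
#' 0.01 for the first third of training, 0.001 for the second, 0.0001 for
#' the last (epochs 1-10 / 11-20 / 21-30 at the default 30 epochs).
#'
#' @param epoch current epoch, `1 <= epoch <= total`.
#' @param total total number of epochs (default 30).
#' @return learning rate.
#' @examples
#' lrSchedule(15)  # 0.001
#' @export
lrSchedule <- function(epoch, total = 30) {
  if (epoch < 1 || epoch > total) stop("epoch out of range [1, ", total, "]")
  stage <- total / 3
  if (epoch <= stage) 0.01 else if (epoch <= 2 * stage) 0.001 else 0.0001
}

#' Training configuration
#'
#' @param epochs number of epochs (default 30).
#' @param batchSize frames per SGD step.
#' @param momentum SGD momentum.
#' @param weightDecay L2 penalty coefficient.
#' @param valFraction fraction of training pairs held out for best-epoch
#'   selection; 0 disables the split and keeps the final epoch's weights.
#' @param augment apply [augment4x()] to the training pairs.
#' @param base,side network width/input side passed to [unetSpec()].
#' @param lambda loss mixing weight, see [combinedLoss()].
#' @param seed seed for weight init, shuffling, and the validation split.
#' @return list of class `trainConfig`.
#' @export
trainConfig <- function(epochs = 30, batchSize = 2, momentum = 0.9,
                        weightDecay = 0, valFraction = 0.1, augment = TRUE,
                        base = 64, side = 576, lambda = 0.5, seed = 1L) {
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 momentum = momentum, weightDecay = weightDecay,
                 valFraction = valFraction, augment = isTRUE(augment),
                 base = base, side = as.integer(side), lambda = lambda,
                 seed = as.integer(seed)), class = "trainConfig")
}

# Stack a list of matrices (0-255) into a (H, W, N, 1) batch on [0, 1].
stackBatch <- function(mats) {
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]])
  array(unlist(mats, use.names = FALSE), c(H, W, length(mats), 1)) / 255
}

sgdStep <- function(params, grads, vel, lr, momentum, weightDecay) {
  for (blk in names(grads)) {
    for (nm in names(grads[[blk]])) {
      g <- grads[[blk]][[nm]]
      if (weightDecay > 0) g <- g + weightDecay * params[[blk]][[nm]]
      v <- momentum * vel[[blk]][[nm]] + g
      vel[[blk]][[nm]] <- v
      params[[blk]][[nm]] <- params[[blk]][[nm]] - lr * v
    }
  }
  list(params = params, vel = vel)
}

hardDice <- function(pred, truth) {
  inter <- sum(pred & truth)
  denom <- sum(pred) + sum(truth)
  if (denom == 0) 1 else 2 * inter / denom
}

#' Train one channel's network
#'
#' Runs SGD with momentum on the combined Dice + weighted cross-entropy
#' loss over (enhanced image, label) pairs. With a validation fraction the
#' weights of the epoch with the best held-out hard Dice are kept; the
#' epoch log records learning rate and the Dice / cross-entropy / total
#' loss components. Fully reproducible for a fixed seed.
#'
#' @param images list of enhanced grayscale matrices on 0-255 (all the same
#'   square size, side divisible by 16).
#' @param labels list of logical (or 0/1) matrices matching `images`.
#' @param cfg a [trainConfig()].
#' @return list with `model` (a [UNetModel-class]), `log` (one row per
#'   epoch: epoch, lr, dice, ce, total, valDice) and `bestEpoch`.
#' @export
trainChannel <- function(images, labels, cfg = trainConfig()) {
  if (length(images) == 0) stop("empty training set")
  if (length(images) != length(labels)) stop("images/labels length mismatch")
  pairs <- mapply(function(im, lb) list(image = im, label = lb * 1),
                  images, labels, SIMPLIFY = FALSE)
  if (cfg$augment) pairs <- augment4x(pairs)

  set.seed(stageSeed(cfg$seed, "split"))
  nVal <- floor(cfg$valFraction * length(pairs))
  valIdx <- if (nVal > 0) sample(length(pairs), nVal) else integer()
  valPairs <- pairs[valIdx]
  trPairs <- if (nVal > 0) pairs[-valIdx] else pairs
  if (length(trPairs) == 0) stop("empty training set after validation split")

  side <- nrow(trPairs[[1]]$image)
  model <- buildUNet(unetSpec(base = cfg$base, side = side), seed = cfg$seed)
  vel <- rapply(model@params, function(x) x * 0, how = "replace")

  log <- data.frame()
  bestVal <- -Inf; bestParams <- model@params; bestBuffers <- model@buffers
  bestEpoch <- 0L
  set.seed(stageSeed(cfg$seed, "epochs"))
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lrSchedule(epoch, cfg$epochs)
    ord <- sample(length(trPairs))
    sums <- c(dice = 0, ce = 0, total = 0); nb <- 0L
    for (start in seq(1, length(ord), by = cfg$batchSize)) {
      idx <- ord[start:min(start + cfg$batchSize - 1L, length(ord))]
      x <- stackBatch(lapply(trPairs[idx], `[[`, "image"))
      yv <- as.numeric(unlist(lapply(trPairs[idx], `[[`, "label"),
                              use.names = FALSE))
      fw <- unetForward(model, x, training = TRUE)
      model <- fw$model
      pv <- as.numeric(fw$p)
      ld <- diceLoss(pv, yv)
      lc <- weightedCrossEntropy(pv, yv)
      tot <- ld + cfg$lambda * lc
      if (!is.finite(tot)) stop("NaN/Inf loss at epoch ", epoch,
                                " (lr ", lr, ")")
      gl <- combinedLossGrad(pv, yv, cfg$lambda)
      grads <- unetBackward(model, fw, array(gl, dim(fw$p)))
      upd <- sgdStep(model@params, grads, vel, lr, cfg$momentum,
                     cfg$weightDecay)
      model@params <- upd$params
      vel <- upd$vel
      sums <- sums + c(ld, lc, tot); nb <- nb + 1L
    }
    valDice <- NA_real_
    if (length(valPairs) > 0) {
      valDice <- mean(vapply(valPairs, function(pr) {
        pm <- predictChannel(model, pr$image)
        hardDice(pm >= 0.5, pr$label > 0.5)
      }, numeric(1)))
      if (valDice > bestVal) {
        bestVal <- valDice; bestParams <- model@params
        bestBuffers <- model@buffers; bestEpoch <- epoch
      }
    }
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 dice = sums[1] / nb, ce = sums[2] / nb,
                                 total = sums[3] / nb, valDice = valDice,
                                 row.names = NULL))
  }
  if (length(valPairs) > 0) {
    model@params <- bestParams
    model@buffers <- bestBuffers
  } else bestEpoch <- cfg$epochs
  list(model = model, log = log, bestEpoch = bestEpoch)
}

#' Predict a probability map for one image
#'
#' Inference-mode forward pass (running batch-norm statistics, no dropout of
#' any kind): deterministic, repeated calls are bit-identical.
#'
#' @param model a trained [UNetModel-class].
#' @param g grayscale matrix on 0-255, square with side divisible by 16.
#' @return matrix of vessel probabilities in `(0, 1)`.
#' @export
predictChannel <- function(model, g) {
  stopifnotMatrix(g)
  x <- array(g / 255, c(nrow(g), ncol(g), 1, 1))
  fw <- unetForward(model, x, training = FALSE)
  matrix(fw$p, nrow(g), ncol(g))
}
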