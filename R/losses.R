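# Training objective: soft Dice loss plus lambda-weighted class-balanced
# cross-entropy (lambda = 0.5). The cross-entropy weights are the false
# discovery rates of the current hard decisions — 1 - TP/Np on the positive
# term and 1 - TN/Nn on the negative term — recomputed per batch from the
# predictions thresholded at 0.5, with no gradient through the weights.

LOSS_EPS <- 1e-7

checkProbLabel <- function(p, q) {
  if (length(p) != length(q)) stop("prediction and label shapes must match")
  if (min(p) < 0 || max(p) > 1) stop("predicted probabilities must lie in [0,1]")
  invisible(TRUE)
}

#' Soft Dice loss
#'
#' `1 - 2*sum(p*q) / (sum(p^2) + sum(q^2) + eps)`: 0 for a perfect binary
#' match, 1 for disjoint nonempty binary maps.
#'
#' @param p predicted probabilities in `[0, 1]`.
#' @param q binary labels (0/1), same shape.
#' @param eps denominator smoothing.
#' @return scalar loss in `[0, 1]` (up to `eps`).
#' @examples
#' diceLoss(c(0.5, 0.5, 0.5, 0.5), c(1, 1, 0, 0))  # 1/3
#' @export
diceLoss <- function(p, q, eps = LOSS_EPS) {
  checkProbLabel(p, q)
  if (!all(q %in% c(0, 1))) stop("labels must be two-valued (0/1)")
  1 - 2 * sum(p * q) / (sum(p * p) + sum(q * q) + eps)
}

#' Class-weighted binary cross-entropy
#'
#' The positive term is weighted by `1 - TP/Np` and the negative term by
#' `1 - TN/Nn`, where Np/Nn are the predicted-positive/negative counts and
#' TP/TN the correct ones, all derived from `p` thresholded at 0.5. The sum
#' is divided by the pixel count so the magnitude is resolution-independent.
#' When a class is never predicted (`Np` or `Nn` zero) its weight defaults
#' to 1.
#'
#' @param p predicted probabilities in `[0, 1]`.
#' @param y binary labels (0/1).
#' @param eps probability clamp for the logarithms.
#' @return non-negative scalar loss.
#' @export
weightedCrossEntropy <- function(p, y, eps = LOSS_EPS) {
  checkProbLabel(p, y)
  if (!all(y %in% c(0, 1))) stop("labels must be two-valued (0/1)")
  w <- ceWeights(p, y)
  pc <- pmin(pmax(p, eps), 1 - eps)
  -mean(w$wpos * y * log(pc) + w$wneg * (1 - y) * log(1 - pc))
}

ceWeights <- function(p, y) {
  hard <- p >= 0.5
  np <- sum(hard); nn <- sum(!hard)
  tp <- sum(hard & y == 1); tn <- sum(!hard & y == 0)
  wpos <- if (np > 0) 1 - tp / np else 1
  wneg <- if (nn > 0) 1 - tn / nn else 1
  list(wpos = wpos, wneg = wneg)
}

#' Combined segmentation loss
#'
#' `diceLoss(p, q) + lambda * weightedCrossEntropy(p, q)` with
#' `lambda = 0.5`.
#'
#' @param p predicted probabilities in `[0, 1]`.
#' @param y binary labels (0/1).
#' @param lambda mixing weight, `>= 0`.
#' @param eps smoothing/clamping constant.
#' @return non-negative scalar loss.
#' @export
combinedLoss <- function(p, y, lambda = 0.5, eps = LOSS_EPS) {
  if (lambda < 0) stop("lambda must be >= 0")
  diceLoss(p, y, eps) + lambda * weightedCrossEntropy(p, y, eps)
}

# Analytic gradient of the combined loss with respect to p (weights frozen).
combinedLossGrad <- function(p, y, lambda = 0.5, eps = LOSS_EPS) {
  n <- length(p)
  S <- sum(p * y)
  D <- sum(p * p) + sum(y * y) + eps
  gDice <- -2 * y / D + 4 * p * S / D^2
  w <- ceWeights(p, y)
  pc <- pmin(pmax(p, eps), 1 - eps)
  gCe <- -(w$wpos * y / pc - w$wneg * (1 - y) / (1 - pc)) / n
  gDice + lambda * gCe
}
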