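# Evaluation suite: pixel confusion counts, Se/Sp/ACC and the balanced-
# accuracy AUC, the Matthews correlation coefficient, and the
# connectivity-area-length (CAL) triple.

#' Pixel confusion counts
#'
#' TP/FP/TN/FN between a predicted and a ground-truth mask, restricted to an
#' evaluation region (typically the FOV). Vessel is the positive class.
#'
#' @param pred,gt logical matrices of identical dims.
#' @param region optional logical matrix; `NULL` evaluates the whole frame.
#' @return list of class `confusionCounts` with `TP`, `FP`, `TN`, `FN`, `n`.
#' @export
confusionCounts <- function(pred, gt, region = NULL) {
  sameDims(pred, gt, "pred and gt")
  if (is.null(region)) region <- matrix(TRUE, nrow(pred), ncol(pred))
  sameDims(pred, region, "masks and region")
  if (!any(region)) stop("empty evaluation region")
  p <- pred[region]; g <- gt[region]
  structure(list(TP = sum(p & g), FP = sum(p & !g),
                 TN = sum(!p & !g), FN = sum(!p & g),
                 n = sum(region)), class = "confusionCounts")
}

#' Sensitivity, specificity, accuracy, and balanced-accuracy AUC
#'
#' `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `ACC = (TP+TN)/n`, and
#' `AUC = (Se+Sp)/2` — the balanced accuracy, not a ROC-curve area. A zero
#' denominator yields `NA` for that metric rather than an error.
#'
#' @param cc a [confusionCounts()].
#' @return list of class `metricsReport` with `Se`, `Sp`, `ACC`, `AUC`.
#' @export
basicMetrics <- function(cc) {
  se <- if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else NA_real_
  sp <- if (cc$TN + cc$FP > 0) cc$TN / (cc$TN + cc$FP) else NA_real_
  acc <- (cc$TP + cc$TN) / cc$n
  auc <- if (is.na(se) || is.na(sp)) NA_real_ else (se + sp) / 2
  structure(list(Se = se, Sp = sp, ACC = acc, AUC = auc),
            class = "metricsReport")
}

#' Matthews correlation coefficient
#'
#' Standard form `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' 0 by convention when any marginal sum is zero. `printedVariant = TRUE`
#' swaps the numerator for `TP*TN - TP*FN` for auditing against reports
#' that use that non-standard expression.
#'
#' @param cc a [confusionCounts()].
#' @param printedVariant use the non-standard numerator.
#' @return value in `[-1, 1]`.
#' @export
mccScore <- function(cc, printedVariant = FALSE) {
  tp <- as.numeric(cc$TP); tn <- as.numeric(cc$TN)
  fp <- as.numeric(cc$FP); fn <- as.numeric(cc$FN)
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) {
    message("MCC undefined (zero marginal); returning 0 by convention")
    return(0)
  }
  num <- if (printedVariant) tp * tn - tp * fn else tp * tn - fp * fn
  num / sqrt(denom2)
}

#' Homotopic skeletonization
#'
#' Iterative two-subiteration thinning (Guo-Hall) that peels a binary shape
#' down to unit-width centerlines while preserving the 8-connectivity of
#' the foreground — the realization of homotopic skeletonization used by
#' the length term of [calMetrics()].
#'
#' @param mask logical matrix.
#' @return logical matrix of centerlines.
#' @export
skeletonizeMask <- function(mask) {
  stopifnotMatrix(mask, "mask")
  m <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  h <- nrow(m); w <- ncol(m)
  ri <- 2:(h - 1L); ci <- 2:(w - 1L)
  repeat {
    changed <- FALSE
    for (iter in 1:2) {
      p <- m[ri, ci]
      P2 <- m[ri - 1L, ci];      P3 <- m[ri - 1L, ci + 1L]
      P4 <- m[ri, ci + 1L];      P5 <- m[ri + 1L, ci + 1L]
      P6 <- m[ri + 1L, ci];      P7 <- m[ri + 1L, ci - 1L]
      P8 <- m[ri, ci - 1L];      P9 <- m[ri - 1L, ci - 1L]
      C <- (!P2 & (P3 | P4)) + (!P4 & (P5 | P6)) +
           (!P6 & (P7 | P8)) + (!P8 & (P9 | P2))
      N1 <- (P9 | P2) + (P3 | P4) + (P5 | P6) + (P7 | P8)
      N2 <- (P2 | P3) + (P4 | P5) + (P6 | P7) + (P8 | P9)
      N <- pmin(N1, N2)
      m2 <- if (iter == 1) (P6 | P7 | !P9) & P8 else (P2 | P3 | !P5) & P4
      del <- p & C == 1 & N >= 2 & N <= 3 & !m2
      if (any(del)) {
        changed <- TRUE
        p[del] <- FALSE
        m[ri, ci] <- p
      }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
}

#' Connectivity-area-length score
#'
#' `CAL = C * A * L` with, for segmentation `S` against ground truth `S_G`:
#' \itemize{
#' \item `C = 1 - min(1, |#C(S_G) - #C(S)| / #(S_G))`, comparing 8-connected
#'   component counts (fragmentation);
#' \item `A = #((d_a(S) & S_G) | (d_a(S_G) & S)) / #(S | S_G)`, overlap of
#'   disc-dilated areas (`d_a` = dilation by a disc of radius `alpha`);
#' \item `L = #((phi(S) & d_b(S_G)) | (d_b(S) & phi(S_G))) /
#'   #(phi(S) | phi(S_G))`, agreement of skeleton lengths within a `beta`
#'   dilation (`phi` = homotopic skeletonization).
#' }
#' Equals 1 when `S == S_G`; 0 when `S` is empty.
#'
#' @param S predicted logical mask.
#' @param SG ground-truth logical mask (nonempty).
#' @param alpha,beta dilation disc radii (default 2 and 2).
#' @return list of class `calReport` with `C`, `A`, `L`, `CAL`.
#' @export
calMetrics <- function(S, SG, alpha = 2, beta = 2) {
  sameDims(S, SG, "S and SG")
  if (!any(SG)) stop("ground truth must be nonempty")
  nCS <- if (any(S)) max(labelComponents(S)) else 0L
  nCG <- max(labelComponents(SG))
  C <- 1 - min(1, abs(nCG - nCS) / sum(SG))
  if (!any(S)) {
    A <- 0; L <- 0
  } else {
    dS <- dilateDisc(S, alpha); dG <- dilateDisc(SG, alpha)
    A <- sum((dS & SG) | (dG & S)) / sum(S | SG)
    phS <- skeletonizeMask(S); phG <- skeletonizeMask(SG)
    dSb <- dilateDisc(S, beta); dGb <- dilateDisc(SG, beta)
    denomL <- sum(phS | phG)
    L <- if (denomL == 0) 1 else sum((phS & dGb) | (dSb & phG)) / denomL
  }
  structure(list(C = C, A = A, L = L, CAL = C * A * L), class = "calReport")
}

#' Per-image evaluation report
#'
#' Evaluates each prediction against its ground truth (inside the FOV when
#' provided) and appends an `Avg.` row of column means — the layout used by
#' per-image benchmark tables.
#'
#' @param preds,gts lists of logical matrices.
#' @param fovs optional list of logical FOV masks (or `NULL`).
#' @param ids character image identifiers.
#' @param cal also compute the (slower) MCC and CAL columns.
#' @return data.frame with columns `Image`, `ACC`, `Se`, `Sp`, `AUC` and
#'   optionally `MCC`, `CAL`.
#' @export
evaluationReport <- function(preds, gts, fovs = NULL, ids = NULL,
                             cal = FALSE) {
  n <- length(preds)
  if (length(gts) != n) stop("preds/gts length mismatch")
  ids <- ids %||% sprintf("img%02d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    cc <- confusionCounts(preds[[i]], gts[[i]],
                          if (is.null(fovs)) NULL else fovs[[i]])
    bm <- basicMetrics(cc)
    row <- data.frame(Image = ids[i], ACC = bm$ACC, Se = bm$Se, Sp = bm$Sp,
                      AUC = bm$AUC)
    if (cal) {
      row$MCC <- mccScore(cc)
      row$CAL <- calMetrics(preds[[i]], gts[[i]])$CAL
    }
    row
  })
  out <- do.call(rbind, rows)
  avg <- out[1, , drop = FALSE]
  avg$Image <- "Avg."
  for (colnm in setdiff(names(out), "Image")) avg[[colnm]] <- mean(out[[colnm]])
  rbind(out, avg)
}

#' Published per-image reference scores
#'
#' Ships the per-image evaluation table of the published multichannel
#' method on the DRIVE, STARE and CHASE_DB1 test sets, plus its per-channel
#' summary on DRIVE. Used by the internal-consistency checks of the metric
#' implementations (e.g. that `(Se+Sp)/2` reproduces the printed AUC
#' column).
#'
#' @param table `"per_image"` or `"channels"`.
#' @return data.frame.
#' @export
referenceScores <- function(table = c("per_image", "channels")) {
  table <- match.arg(table)
  f <- system.file("extdata", paste0("reference_", table, ".csv"),
                   package = "VesselFuse", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
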