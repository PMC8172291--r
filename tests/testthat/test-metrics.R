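test_that("confusion counts match exhaustive enumeration", {
  gt <- matrix(FALSE, 3, 3); gt[1, 1] <- TRUE; gt[2, 2] <- TRUE
  pred <- matrix(FALSE, 3, 3); pred[1, 1] <- TRUE; pred[3, 3] <- TRUE
  cc <- confusionCounts(pred, gt)
  expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")]),
               c(TP = 1L, FP = 1L, TN = 6L, FN = 1L))
  expect_equal(cc$n, 9L)
  # perfect and inverted predictions
  p <- matrix(runif(64) > 0.5, 8, 8)
  self <- confusionCounts(p, p)
  expect_equal(self$FP + self$FN, 0L)
  inv <- confusionCounts(!p, p)
  expect_equal(inv$TP + inv$TN, 0L)
  # restriction to a region
  reg <- matrix(FALSE, 3, 3); reg[1, ] <- TRUE
  cr <- confusionCounts(pred, gt, reg)
  expect_equal(cr$n, 3L)
  expect_equal(cr$TP, 1L)
  expect_error(confusionCounts(pred, gt, matrix(FALSE, 3, 3)), "empty")
  expect_error(confusionCounts(pred, matrix(FALSE, 2, 2)), "dimensions")
})

test_that("basic metrics follow their definitions on hand-computed counts", {
  cc <- structure(list(TP = 3, FP = 1, TN = 4, FN = 2, n = 10),
                  class = "confusionCounts")
  bm <- basicMetrics(cc)
  expect_equal(bm$Se, 0.6)
  expect_equal(bm$Sp, 0.8)
  expect_equal(bm$ACC, 0.7)
  expect_equal(bm$AUC, 0.7)
  perfect <- basicMetrics(structure(list(TP = 5, FP = 0, TN = 5, FN = 0,
                                         n = 10), class = "confusionCounts"))
  expect_equal(unlist(perfect), c(Se = 1, Sp = 1, ACC = 1, AUC = 1))
  # zero denominator flags the metric as undefined instead of erroring
  noPos <- basicMetrics(structure(list(TP = 0, FP = 0, TN = 9, FN = 0,
                                       n = 9), class = "confusionCounts"))
  expect_true(is.na(noPos$Se))
  expect_true(is.na(noPos$AUC))
})

test_that("the AUC is identically balanced accuracy and ACC is swap-invariant", {
  set.seed(13)
  for (i in 1:20) {
    v <- sample(0:50, 4, replace = TRUE) + 1
    cc <- structure(list(TP = v[1], FP = v[2], TN = v[3], FN = v[4],
                         n = sum(v)), class = "confusionCounts")
    bm <- basicMetrics(cc)
    expect_equal(bm$AUC, (bm$Se + bm$Sp) / 2)
    sw <- structure(list(TP = v[3], FP = v[4], TN = v[1], FN = v[2],
                         n = sum(v)), class = "confusionCounts")
    expect_equal(basicMetrics(sw)$ACC, bm$ACC)
  }
})

test_that("published per-channel rows satisfy the (Se+Sp)/2 identity to 4 decimals", {
  tab <- referenceScores("channels")
  expect_equal(nrow(tab), 4)
  expect_true(all(abs((tab$Se + tab$Sp) / 2 - tab$AUC) <= 5.1e-5))
})

test_that("published per-image averages are internally consistent", {
  tab <- referenceScores("per_image")
  drive <- tab[tab$dataset == "DRIVE", ]
  expect_equal(nrow(drive), 20)
  expect_equal(round(mean(drive$ACC), 3), 0.955)
  stare <- tab[tab$dataset == "STARE", ]
  expect_equal(nrow(stare), 5)
  expect_equal(round(mean(stare$AUC), 3), 0.932)
})

test_that("MCC matches hand arithmetic, its extremes, and the audit variant", {
  cc <- structure(list(TP = 3, FP = 1, TN = 4, FN = 2, n = 10),
                  class = "confusionCounts")
  expect_equal(mccScore(cc), (12 - 2) / sqrt(4 * 5 * 5 * 6))
  expect_equal(mccScore(cc), 0.4082, tolerance = 2e-4)
  perfect <- structure(list(TP = 5, FP = 0, TN = 5, FN = 0, n = 10),
                       class = "confusionCounts")
  expect_equal(mccScore(perfect), 1)
  inverted <- structure(list(TP = 0, FP = 5, TN = 0, FN = 5, n = 10),
                        class = "confusionCounts")
  expect_equal(mccScore(inverted), -1)
  # the audit variant swaps the numerator
  expect_equal(mccScore(cc, printedVariant = TRUE),
               (12 - 6) / sqrt(4 * 5 * 5 * 6))
  degenerate <- structure(list(TP = 0, FP = 0, TN = 10, FN = 0, n = 10),
                          class = "confusionCounts")
  expect_message(v <- mccScore(degenerate), "convention")
  expect_equal(v, 0)
})

test_that("skeletonization thins to unit width and preserves connectivity", {
  m <- matrix(FALSE, 20, 20)
  m[5:15, 8:11] <- TRUE  # a thick bar
  sk <- skeletonizeMask(m)
  expect_true(all(sk <= m))
  expect_equal(max(bruteLabel(sk)), 1)
  # a unit-width line is its own skeleton interior
  ln <- matrix(FALSE, 10, 10); ln[5, 2:9] <- TRUE
  expect_equal(max(bruteLabel(skeletonizeMask(ln))), 1)
})

test_that("CAL is exact on identity, emptiness, and the fragmented line", {
  SG <- matrix(FALSE, 15, 30); SG[8, 6:25] <- TRUE  # 20-pixel line
  self <- calMetrics(SG, SG)
  expect_equal(unlist(self), c(C = 1, A = 1, L = 1, CAL = 1))
  empty <- calMetrics(matrix(FALSE, 15, 30), SG)
  expect_equal(empty$A, 0)
  expect_equal(empty$CAL, 0)
  # breaking the line into 3 fragments: C = 1 - |1-3|/20 = 0.9 exactly
  S <- SG; S[8, c(12, 19)] <- FALSE
  frag <- calMetrics(S, SG)
  expect_equal(max(bruteLabel(S)), 3)
  expect_equal(frag$C, 1 - 2 / 20)
  expect_lt(frag$C, 1)
  # A and L recomputed with independent set operations
  dS <- bruteMorph(S * 1, discKernel(2), max) > 0
  dG <- bruteMorph(SG * 1, discKernel(2), max) > 0
  Aref <- sum((dS & SG) | (dG & S)) / sum(S | SG)
  expect_equal(frag$A, Aref)
  phS <- skeletonizeMask(S); phG <- skeletonizeMask(SG)
  Lref <- sum((phS & dG) | (dS & phG)) / sum(phS | phG)
  expect_equal(frag$L, Lref)
  expect_equal(frag$CAL, frag$C * frag$A * frag$L)
  expect_lte(frag$CAL, min(frag$C, frag$A, frag$L))
  expect_error(calMetrics(S, matrix(FALSE, 15, 30)), "nonempty")
})

test_that("the evaluation report carries per-image rows plus an Avg row", {
  set.seed(15)
  gts <- lapply(1:3, function(i) matrix(runif(400) > 0.8, 20, 20))
  preds <- lapply(gts, function(g) g | (matrix(runif(400) > 0.95, 20, 20)))
  rep <- evaluationReport(preds, gts, ids = c("a", "b", "c"))
  expect_equal(nrow(rep), 4)
  expect_equal(rep$Image[4], "Avg.")
  expect_equal(rep$ACC[4], mean(rep$ACC[1:3]))
  expect_true(all(rep$Se[1:3] == 1))  # predictions are supersets
})
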