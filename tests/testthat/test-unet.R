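test_that("the reference ledger reproduces every printed block count", {
  m <- buildUNet(unetSpec(), seed = 1)
  led <- countParameters(m)
  expect_equal(led$count,
               c(37824L, 221952L, 886272L, 3542016L, 4721664L,
                 2950656L, 738048L, 184704L, 110976L, 65L))
  expect_equal(attr(led, "total"), 13394177)
  expect_equal(nParams(m), 13394177)
  # closed form 9*(C1+C2)*C2 + 6*C2 for the blocks, from real arrays
  expect_equal(doubleConvParams(1, 64), 9 * (1 + 64) * 64 + 6 * 64)
  expect_equal(doubleConvParams(1024, 256), 2950656)
})

test_that("ledger printing shows eleven rows and the total", {
  m <- buildUNet(unetSpec(base = 4, side = 64), seed = 1)
  out <- capture.output(printParamLedger(m))
  expect_length(out, 13)  # header + Input + 9 blocks + Output + Total
  expect_match(out[2], "^Input")
  expect_match(out[13], "^Total")
})

test_that("forward pass preserves dims and yields probabilities", {
  m <- buildUNet(unetSpec(base = 2, side = 64), seed = 7)
  for (side in c(32, 64)) {
    x <- array(0, c(side, side, 1, 1))
    fw <- unetForward(m, x)
    expect_equal(dim(fw$p), dim(x))
    expect_true(all(is.finite(fw$p)))
    expect_true(all(fw$p > 0 & fw$p < 1))
  }
  expect_error(unetForward(m, array(0, c(30, 30, 1, 1))), "divisible")
})

test_that("two builds from one seed are identical, different seeds differ", {
  a <- buildUNet(unetSpec(base = 2, side = 32), seed = 5)
  b <- buildUNet(unetSpec(base = 2, side = 32), seed = 5)
  expect_identical(a@params, b@params)
  c <- buildUNet(unetSpec(base = 2, side = 32), seed = 6)
  expect_false(identical(a@params, c@params))
})

test_that("compiled convolution kernels agree with the plain-R reference", {
  set.seed(12)
  x <- array(rnorm(14 * 10 * 2 * 3), c(14, 10, 2, 3))
  W <- array(rnorm(3 * 3 * 3 * 5) * 0.2, c(3, 3, 3, 5))
  b <- rnorm(5)
  f1 <- VesselFuse:::convForward(x, W, b)
  f2 <- VesselFuse:::convForwardR(x, W, b)
  expect_equal(f1, f2, tolerance = 1e-12)
  dy <- array(rnorm(length(f1)), dim(f1))
  g1 <- VesselFuse:::convBackward(x, W, dy)
  g2 <- VesselFuse:::convBackwardR(x, W, dy)
  expect_equal(g1$dx, g2$dx, tolerance = 1e-12)
  expect_equal(g1$dW, g2$dW, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(g1$db, g2$db, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("network gradients match finite differences", {
  set.seed(42)
  m <- buildUNet(unetSpec(base = 2, side = 32), seed = 3)
  x <- array(runif(32 * 32 * 1), c(32, 32, 1, 1))
  yv <- rbinom(32 * 32, 1, 0.2)
  fw <- unetForward(m, x, training = TRUE)
  m <- fw$model
  gl <- combinedLossGrad(as.numeric(fw$p), yv)
  grads <- VesselFuse:::unetBackward(m, fw, array(gl, dim(fw$p)))
  lossAt <- function(model) {
    f <- unetForward(model, x, training = TRUE)
    combinedLoss(as.numeric(f$p), yv)
  }
  eps <- 1e-5
  for (blk in c("enc1", "enc5", "dec1", "dec4", "out")) {
    for (nm in names(grads[[blk]])[c(1, length(grads[[blk]]))]) {
      arr <- m@params[[blk]][[nm]]
      i <- sample(length(arr), 1)
      mp <- m; mp@params[[blk]][[nm]][i] <- arr[i] + eps
      mm <- m; mm@params[[blk]][[nm]][i] <- arr[i] - eps
      num <- (lossAt(mp) - lossAt(mm)) / (2 * eps)
      ana <- grads[[blk]][[nm]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4,
                label = paste("grad", blk, nm))
    }
  }
})

test_that("checkpoints round-trip and refuse a wrong architecture digest", {
  m <- buildUNet(unetSpec(base = 2, side = 32), seed = 9)
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, f)
  back <- loadModel(f)
  expect_identical(back@params, m@params)
  x <- readRDS(f); x$spec$encoder[1] <- 99L; saveRDS(x, f)
  expect_error(loadModel(f), "digest")
})
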