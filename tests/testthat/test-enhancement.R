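test_that("every kernel in both published banks is zero-mean", {
  for (pars in list(c(10.8, 1.9, 8), c(5, 0.1, 18))) {
    bank <- suppressMessages(buildKernelBank(pars[1], pars[2], pars[3]))
    expect_length(bankKernels(bank), pars[3])
    rel <- vapply(bankKernels(bank),
                  function(k) abs(sum(k)) / sum(abs(k)), numeric(1))
    expect_true(all(rel < 1e-9))
  }
  expect_error(buildKernelBank(10, 1, 0), "nDirs")
  expect_error(buildKernelBank(-1, 1, 4), "positive")
})

test_that("large-scale bank support spans the expected unrotated box", {
  bank <- buildKernelBank(10.8, 1.9, 8)
  sup <- bank@supports[[1]]  # angle 0: u = column offset, v = row offset
  half <- (nrow(sup) - 1) / 2
  offs <- seq(-half, half)
  cols <- which(apply(sup, 2, any)); rows <- which(apply(sup, 1, any))
  # |u| <= 3*1.9 = 5.7, |v| <= 10.8/2 = 5.4; every pixel whose center is
  # inside is in the support, anti-aliasing adds at most the next pixel out
  expect_true(all(-5:5 %in% offs[cols]))
  expect_lte(max(abs(offs[cols])), 6)
  expect_true(all(-5:5 %in% offs[rows]))
  expect_lte(max(abs(offs[rows])), 6)
  # point-sampled construction reproduces the exact box
  bankPt <- buildKernelBank(10.8, 1.9, 8, supersample = 1)
  supPt <- bankPt@supports[[1]]
  colsPt <- which(apply(supPt, 2, any)); rowsPt <- which(apply(supPt, 1, any))
  expect_equal(range(offs[colsPt]), c(-5, 5))
  expect_equal(range(offs[rowsPt]), c(-5, 5))
})

test_that("small-scale bank gets the floored 3-px cross-section with a dark core", {
  expect_message(bank <- buildKernelBank(5, 0.1, 18), "floored")
  sup <- bank@supports[[1]]
  half <- (nrow(sup) - 1) / 2
  offs <- seq(-half, half)
  cols <- which(apply(sup, 2, any)); rows <- which(apply(sup, 1, any))
  expect_equal(range(offs[cols]), c(-1, 1))  # floored |u| <= 1
  expect_equal(range(offs[rows]), c(-2, 2))  # |v| <= 2.5
  k <- bankKernels(bank)[[1]]
  ctr <- half + 1
  expect_true(all(k[cbind(ctr + (-2:2), ctr)] < 0))      # center column dark
  expect_true(all(k[cbind(ctr + (-2:2), ctr - 1)] > 0))  # flanks positive
  # point-sampled hand value: center -exp(0) = -1, flanks -exp(-50) ~ 0,
  # support mean ~ -1/3, unit-energy scaling preserves the sign pattern
  kPt <- bankKernels(suppressMessages(
    buildKernelBank(5, 0.1, 18, supersample = 1)))[[1]]
  expect_equal(kPt[ctr, ctr] / abs(kPt[ctr - 2, ctr - 1]),
               (-1 + 1 / 3) / (1 / 3), tolerance = 1e-4)
})

test_that("correlation agrees with a brute-force oracle and kills constants", {
  bank <- buildKernelBank(4, 1, 4)
  const <- matrix(77, 24, 24)
  raw <- matchedFilterResponse(const, bank, rescale = FALSE)
  expect_lt(max(abs(raw)), 1e-8)

  set.seed(8)
  img <- matrix(runif(26 * 26, 0, 255), 26, 26)
  k <- bankKernels(bank)[[2]]
  mine <- VesselFuse:::correlateKernel(img, k)
  oracle <- bruteCorrelate(img, k)
  expect_equal(mine, oracle, tolerance = 1e-6)
})

test_that("each orientation of the 8-direction bank wins on its own line exactly", {
  bank <- buildKernelBank(10.8, 1.9, 8)
  for (i in 1:8) {
    img <- lineFixture(51, bankAngles(bank)[i], sigma = 2)
    expect_equal(centerWinner(bank, img), i, label = paste("direction", i))
  }
})

test_that("the 18-direction bank resolves every line to its angular resolution", {
  # a 3x5 template cannot discriminate 10-degree steps exactly on the pixel
  # lattice (a point at radius 2.5 moves < 0.5 px under 10 degrees), so the
  # winner must land within one angular step; most orientations are exact
  bank <- suppressMessages(buildKernelBank(5, 0.1, 18))
  wins <- integer(18)
  for (i in 1:18) {
    img <- lineFixture(51, bankAngles(bank)[i], sigma = 0.5)
    wins[i] <- centerWinner(bank, img)
  }
  steps <- vapply(1:18, function(i) circularStep(wins[i], i, 18), numeric(1))
  expect_true(all(steps <= 1))
  expect_gte(sum(steps == 0), 12)
})

test_that("rotating the image by 90 degrees shifts the winning direction by nDirs/2", {
  # bank angles span pi over nDirs steps, so a 90-degree image rotation
  # moves the winner by nDirs/2 positions (mod nDirs)
  bank <- buildKernelBank(10.8, 1.9, 8)
  for (i in c(2, 5)) {
    img <- lineFixture(51, bankAngles(bank)[i], sigma = 2)
    rot <- t(img)[, rev(seq_len(51))]  # 90-degree rotation
    expected <- (i - 1 + 4) %% 8 + 1
    expect_equal(centerWinner(bank, rot), expected)
  }
})

test_that("background removal follows the closing identity on a toy grid", {
  set.seed(3)
  g <- matrix(230, 9, 9)
  g[5, 2:8] <- 60  # one-pixel dark line
  icl <- bruteClosing(g, discKernel(3))
  raw <- 255 - (icl - g) + mean(icl)
  oracle <- (raw - min(raw)) / (max(raw) - min(raw)) * 255
  expect_equal(removeBackgroundClose(g, 3), oracle, tolerance = 1e-6)
  # line pixels end up at the dark end of the range
  expect_lt(max(removeBackgroundClose(g, 3)[5, 2:8]), 10)
  expect_warning(out <- removeBackgroundClose(matrix(50, 8, 8), 3),
                 "degenerate")
  expect_true(all(out == 0))
})

test_that("black hat2 matches the brute-force closing oracle and its contract", {
  const <- matrix(90, 12, 12)
  expect_true(all(blackHat2(const, blackHatConfig(2)) == 255 - 90))

  set.seed(10)
  f <- matrix(200, 7, 7)
  f[4, 4] <- 20  # single dark pixel
  bh <- bruteClosing(f, discKernel(2)) - f
  oracle <- pmin(pmax(255 - (f - 2 * bh), 0), 255)
  expect_equal(blackHat2(f, blackHatConfig(2)), oracle)

  rnd <- matrix(runif(30 * 30, 0, 255), 30, 30)
  out <- blackHat2(rnd, blackHatConfig(3))
  expect_gte(min(out), 0)
  expect_lte(max(out), 255)
})

test_that("channel dispatch is deterministic and scale-selective", {
  p <- smallPhantom(seed = 6)
  gp <- preprocessFundus(phantomImage(p))
  expect_error(enhanceChannel(gp, structure(list(channel = 4),
                                            class = "channelSpec")))
  e2 <- suppressMessages(enhanceChannel(gp, channelSpec(2)))
  expect_identical(e2, suppressMessages(enhanceChannel(gp, channelSpec(2))))

  # two-width phantom: the large-scale channel favors the wide vessel,
  # the small-scale channel the thin one (vessels are dark: lower = stronger)
  wide <- generatePhantom(phantomConfig(side = 128, nVessels = 1,
                                        widthRange = c(6, 6), noiseSigma = 0,
                                        opticDisc = FALSE), seed = 31)
  thin <- generatePhantom(phantomConfig(side = 128, nVessels = 1,
                                        widthRange = c(1, 1), noiseSigma = 0,
                                        opticDisc = FALSE), seed = 31)
  score <- function(ph, chan) {
    g <- preprocessFundus(phantomImage(ph))
    e <- suppressMessages(enhanceChannel(g, channelSpec(chan)))
    bg <- mean(e[phantomFov(ph) & !phantomTruth(ph)])
    bg - mean(e[phantomTruth(ph)])  # dark-vessel contrast
  }
  relWide <- score(wide, 2) / score(wide, 3)
  relThin <- score(thin, 2) / score(thin, 3)
  expect_gt(relWide, relThin)
})

test_that("matched-filter response separates phantom vessels from background", {
  p <- smallPhantom(seed = 14)
  gp <- preprocessFundus(phantomImage(p))
  bank <- buildKernelBank(10.8, 1.9, 8)
  r <- matchedFilterResponse(gp, bank)
  fov <- phantomFov(p)
  expect_gt(mean(r[phantomTruth(p)]), mean(r[fov & !phantomTruth(p)]))
  auc <- rankAuc(r[fov], phantomTruth(p)[fov])
  expect_gt(auc, 0.8)
})
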