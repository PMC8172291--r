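test_that("image write/read round trip is bit-exact for 8-bit images", {
  set.seed(11)
  img <- array(sample(0:255, 24 * 18 * 3, replace = TRUE), c(24, 18, 3))
  f <- withr::local_tempfile(fileext = ".png")
  writeFundus(img, f)
  expect_identical(readFundus(f), img + 0)

  m <- matrix(sample(c(TRUE, FALSE), 30 * 20, replace = TRUE), 30, 20)
  fm <- withr::local_tempfile(fileext = ".png")
  writeMask(m, fm)
  expect_identical(readMask(fm), m)
})

test_that("constant black and white images decode to the expected planes", {
  f <- withr::local_tempfile(fileext = ".png")
  writeFundus(array(0, c(2, 2, 3)), f)
  expect_true(all(readFundus(f) == 0))
  writeFundus(array(255, c(2, 2, 3)), f)
  expect_true(all(readFundus(f) == 255))
  expect_error(readFundus(file.path(tempdir(), "nope.png")), "not found")
})

test_that("extractGreen returns plane 2 and phantom vessels are darker there", {
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- c(10, 200, 30)
  expect_equal(extractGreen(img)[1, 1], 200)

  rep3 <- array(rep(matrix(1:4, 2), 3), c(2, 2, 3))
  expect_equal(extractGreen(rep3), rep3[, , 1])

  p <- smallPhantom(seed = 3)
  g <- extractGreen(phantomImage(p))
  expect_lt(mean(g[phantomTruth(p)]),
            mean(g[phantomFov(p) & !phantomTruth(p)]))
})

test_that("FOV mask recovers the phantom aperture", {
  p <- generatePhantom(phantomConfig(side = 256), seed = 21)
  r <- 0.48 * 256
  # without the erosion margin the area should match the analytic disc
  fov0 <- makeFovMask(phantomImage(p), erodeRadius = 0)
  expect_lt(abs(sum(fov0) - pi * r^2) / (pi * r^2), 0.05)
  # the default margin pulls the boundary inward, never outward
  fov3 <- makeFovMask(phantomImage(p))
  expect_true(all(fov3 <= fov0))
  expect_lt(abs(sum(fov3) - pi * (r - 3)^2) / (pi * r^2), 0.05)
  # near-idempotence: masking the image and re-extracting moves at most a
  # thin boundary band (blur + Otsu see a slightly sharper edge)
  masked <- phantomImage(p)
  for (k in 1:3) masked[, , k][!fov3] <- 0
  again <- makeFovMask(masked)
  expect_gte(mean(again == fov3), 0.95)
})

test_that("FOV extraction fails loudly on degenerate frames", {
  expect_error(makeFovMask(array(0, c(32, 32, 3))), "empty")
  bright <- makeFovMask(array(250, c(32, 32, 3)))
  expect_gt(sum(bright), 0.6 * 32 * 32)  # full frame minus the margin
})

test_that("network frame mapping is invertible on dimensions", {
  g <- matrix(runif(576 * 576, 0, 255), 576, 576)
  expect_equal(toNetworkFrame(g), g, ignore_attr = TRUE)

  g2 <- matrix(runif(584 * 565, 0, 255), 584, 565)
  fr <- toNetworkFrame(g2)
  expect_equal(dim(fr), c(576, 576))
  expect_equal(attr(fr, "origDim"), c(584L, 565L))
  back <- fromNetworkFrame(fr, attr(fr, "origDim"))
  expect_equal(dim(back), c(584, 565))

  g3 <- matrix(runif(960 * 999), 960, 999)
  expect_equal(dim(fromNetworkFrame(toNetworkFrame(g3), c(960, 999))),
               c(960, 999))
  # binary restoration keeps masks two-valued
  mk <- fromNetworkFrame(matrix(runif(576^2) > 0.9, 576), c(584, 565),
                         binary = TRUE)
  expect_type(mk, "logical")
  expect_error(toNetworkFrame(matrix(numeric(0), 0, 0)), "positive")
})

test_that("dataset splits are disjoint with the published sizes and ids", {
  for (ds in c("DRIVE", "STARE", "CHASE_DB1")) {
    sp <- datasetSplit(ds)
    expect_length(intersect(sp$train, sp$test), 0)
  }
  expect_equal(lengths(datasetSplit("DRIVE")[c("train", "test")]),
               c(train = 20L, test = 20L))
  expect_setequal(datasetSplit("STARE")$test,
                  c("im0002", "im0077", "im0163", "im0255", "im0291"))
  expect_length(datasetSplit("STARE")$train, 15)
  chase <- datasetSplit("CHASE_DB1")
  expect_length(chase$train, 20)
  expect_length(chase$test, 8)
})

test_that("manifests round-trip through YAML", {
  items <- data.frame(id = c("a", "b"), split = c("train", "test"),
                      image = c("a.png", "b.png"), label = c("ag.png", "bg.png"),
                      fov = c("af.png", "bf.png"), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".yaml")
  writeManifest(list(name = "toy", items = items), f)
  back <- readManifest(f)
  expect_equal(back$name, "toy")
  expect_equal(back$items, items, ignore_attr = TRUE)
})
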