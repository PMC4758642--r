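test_that("Otsu separates a two-level image and matches exhaustive search", {
  img <- matrix(c(rep(10, 60), rep(100, 40)), 10, 10)
  th <- autoThreshold(img)
  expect_gt(th$threshold, 10)
  expect_lt(th$threshold, 100)
  expect_identical(th$mask, img > th$threshold)
  expect_equal(sum(th$mask), 40L)

  ## brute-force oracle over all 256 candidate levels, several random images
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rgamma(400, 2, 1) + c(rep(0, 300), rep(8, 100)), 20, 20)
    expect_equal(autoThreshold(x)$threshold, otsuOracle(x), tolerance = 1e-9)
    ## independent library cross-check, agreement to within one bin width
    if (requireNamespace("EBImage", quietly = TRUE)) {
      mn <- min(x); mx <- max(x)
      ref <- mn + (mx - mn) *
        EBImage::otsu(EBImage::Image((x - mn) / (mx - mn)), c(0, 1), 256)
      expect_lt(abs(autoThreshold(x)$threshold - ref), (mx - mn) / 256 * 8)
    }
  }
})

test_that("constant image under Otsu raises a degenerate-histogram error", {
  expect_error(autoThreshold(matrix(5, 4, 4)), "degenerate histogram")
})

test_that("percentile threshold retains exactly the requested pixel count", {
  set.seed(1)
  x <- matrix(sample(1:5000, 10000, replace = TRUE), 100, 100)
  th <- autoThreshold(x, "percentile", percentile = 0.05)
  expect_equal(sum(th$mask), 500L)
  ## the retained pixels are the brightest ones
  expect_true(min(x[th$mask]) >= max(x[!th$mask]) - 0)
  expect_equal(th$threshold, min(x[th$mask]))
})

test_that("detectPuncta recovers well-separated synthetic spots", {
  sim <- makePunctaImage(simImageSpec(nPuncta = 12L, noiseSd = 0))
  th <- autoThreshold(sim$image)
  ps <- detectPuncta(th$mask, sim$image, threshold = th$threshold)
  expect_equal(punctaCount(ps), 12L)
  ## centroids within 1 px of ground truth
  got <- sort(punctaTable(ps)$xUm)
  want <- sort(sim$truth$puncta$xUm)
  expect_true(all(abs(got - want) < 0.16))
  gotY <- punctaTable(ps)$yUm
  expect_true(all(abs(gotY - sim$truth$puncta$yUm[1]) < 0.16))
})

test_that("blank mask, min-area filtering and merged components behave as defined", {
  img <- FluorImage(matrix(1, 10, 10))
  expect_equal(punctaCount(detectPuncta(matrix(FALSE, 10, 10), img)), 0L)
  ## a 2-pixel blob is dropped at minArea = 4, kept at minArea = 2
  m <- matrix(FALSE, 10, 10); m[5, 5:6] <- TRUE
  expect_equal(punctaCount(detectPuncta(m, img, minArea = 4L)), 0L)
  expect_equal(punctaCount(detectPuncta(m, img, minArea = 2L)), 1L)
  ## two touching spots merge into one component (documented limitation)
  m2 <- matrix(FALSE, 10, 10); m2[4:6, 4:5] <- TRUE; m2[4:6, 6:7] <- TRUE
  expect_equal(punctaCount(detectPuncta(m2, img, minArea = 4L)), 1L)
  ## diagonal-only contact: joined under 8-connectivity, split under 4
  m3 <- matrix(FALSE, 10, 10); m3[2:3, 2:3] <- TRUE; m3[4:5, 4:5] <- TRUE
  expect_equal(punctaCount(detectPuncta(m3, img, connectivity = 8L)), 1L)
  expect_equal(punctaCount(detectPuncta(m3, img, connectivity = 4L)), 2L)
  expect_error(detectPuncta(matrix(FALSE, 3, 3), img), "dimension mismatch")
})

test_that("density arithmetic, scale invariance, and translation invariance", {
  sim <- makePunctaImage(simImageSpec(nPuncta = 12L, noiseSd = 0))
  ps <- detectPuncta(autoThreshold(sim$image)$mask, sim$image)
  expect_equal(punctaDensity(ps, 60), 20)
  expect_equal(punctaDensity(ps, 120) * 2, punctaDensity(ps, 60))
  empty <- detectPuncta(matrix(FALSE, 4, 4), FluorImage(matrix(1, 4, 4)))
  expect_equal(punctaDensity(empty, 50), 0)
  expect_error(punctaDensity(ps, 0), "positive")

  ## translating the image along the cord leaves the count unchanged
  x <- intensities(sim$image)
  shifted <- FluorImage(cbind(x[, 41:ncol(x)], x[, 1:40]), pixelSize(sim$image))
  ps2 <- detectPuncta(autoThreshold(shifted)$mask, shifted)
  expect_equal(punctaCount(ps2), punctaCount(ps))
})

test_that("integrated density matches a per-pixel loop and is additive", {
  ## uniform value 2 over a 10-pixel region, threshold 0 -> 20
  img <- matrix(2, 8, 8)
  region <- matrix(FALSE, 8, 8); region[2, 1:5] <- TRUE; region[3, 1:5] <- TRUE
  expect_equal(integratedDensity(img, region), 20)
  ## all-subthreshold region -> 0
  expect_equal(integratedDensity(img, region, threshold = 5), 0)

  set.seed(9)
  x <- matrix(runif(400, 0, 100), 20, 20)
  m <- matrix(runif(400) < 0.3, 20, 20)
  thr <- 40
  loop <- 0
  for (i in 1:20) for (j in 1:20)
    if (m[i, j] && x[i, j] > thr) loop <- loop + x[i, j]
  expect_equal(integratedDensity(x, m, thr), loop)

  ## additivity over disjoint regions
  mA <- m & (row(m) <= 10); mB <- m & (row(m) > 10)
  expect_equal(integratedDensity(x, mA, thr) + integratedDensity(x, mB, thr),
               integratedDensity(x, m, thr))
})

test_that("circular ROI selects the expected pixels and respects bounds", {
  img <- matrix(1, 20, 20)
  roi <- roiCircle(10, 10, 3)
  ## area close to pi r^2
  expect_equal(integratedDensity(img, roi), sum(
    (rep(1:20, each = 20) - 0.5 - 10)^2 +
    (rep(1:20, 20) - 0.5 - 10)^2 <= 9))
  expect_error(integratedDensity(img, roiCircle(100, 100, 2)),
               "outside the image")
  expect_error(roiCircle(1, 1, 0), "positive")
})
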