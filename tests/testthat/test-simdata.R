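test_that("noise-free image with no puncta is identically the background", {
  sim <- makePunctaImage(simImageSpec(widthPx = 64L, heightPx = 16L,
                                      nPuncta = 0L, noiseSd = 0))
  expect_true(all(intensities(sim$image) == 10))
  expect_equal(nrow(sim$truth$puncta), 0L)
})

test_that("ground truth carries every centroid and yields the expected density", {
  ## 12 puncta over a 60 um cord (375 px at 0.16 um/px) -> 20 per 100 um
  sim <- makePunctaImage(simImageSpec(widthPx = 375L, nPuncta = 12L,
                                      noiseSd = 0))
  expect_equal(nrow(sim$truth$puncta), 12L)
  expect_equal(sim$truth$cordLengthUm, 60)
  ps <- detectPuncta(autoThreshold(sim$image)$mask, sim$image)
  expect_equal(punctaCount(ps), 12L)
  expect_equal(punctaDensity(ps, 60), 20)
})

test_that("simulation is bit-identical under a fixed seed", {
  s1 <- makePunctaImage(simImageSpec(seed = 42L))
  s2 <- makePunctaImage(simImageSpec(seed = 42L))
  expect_identical(intensities(s1$image), intensities(s2$image))
  expect_identical(s1$truth, s2$truth)
  s3 <- makePunctaImage(simImageSpec(seed = 43L))
  expect_false(identical(intensities(s1$image), intensities(s3$image)))

  m1 <- makeMovie(simMovieSpec(frames = 20L, seed = 7L))
  m2 <- makeMovie(simMovieSpec(frames = 20L, seed = 7L))
  expect_identical(intensities(m1$movie), intensities(m2$movie))
  expect_identical(m1$truth, m2$truth)

  l1 <- makeLambdaStack(matrix(1, 4, 4), matrix(1, 4, 4), noiseSd = 0.1,
                        seed = 3L)
  l2 <- makeLambdaStack(matrix(1, 4, 4), matrix(1, 4, 4), noiseSd = 0.1,
                        seed = 3L)
  expect_identical(intensities(l1$stack), intensities(l2$stack))
})

test_that("invalid specs are rejected", {
  expect_error(simImageSpec(widthPx = 0), "positive")
  expect_error(simImageSpec(pixelSizeUm = -1), "positive")
  expect_error(simImageSpec(nPuncta = -1), "non-negative")
  expect_error(makeTwoChannelImage(simImageSpec(), 1.5), "\\[0, 1\\]")
  expect_error(makeTwoChannelImage(simImageSpec(), -0.1), "\\[0, 1\\]")
  expect_error(simMovieSpec(frames = 1L), "between 2 and 500")
  expect_error(simMovieSpec(vesicles = vesicleSpec(999, 1)), "outside cord")
})

test_that("two-channel truth matches the requested sharing structure", {
  spec <- simImageSpec(nPuncta = 16L, noiseSd = 0)
  tw <- makeTwoChannelImage(spec, 0.75)
  tab <- tw$truth$puncta
  expect_equal(sum(tab$type == "shared"), 12L)
  expect_equal(sum(tab$type == "ch1"), 4L)
  expect_equal(sum(tab$type == "ch2"), 4L)
  ## identical channels at colocFraction = 1
  tw1 <- makeTwoChannelImage(spec, 1)
  expect_identical(intensities(tw1$ch1), intensities(tw1$ch2))
  ## disjoint positions at colocFraction = 0: no pixel is bright in both
  tw0 <- makeTwoChannelImage(spec, 0)
  both <- intensities(tw0$ch1) > 60 & intensities(tw0$ch2) > 60
  expect_equal(sum(both), 0L)
})

test_that("offset non-shared puncta land at the stated displacement", {
  tw <- makeTwoChannelImage(simImageSpec(nPuncta = 10L, noiseSd = 0), 0,
                            offsetUm = 0.8)
  tab <- tw$truth$puncta
  x1 <- sort(tab$xUm[tab$type == "ch1"])
  x2 <- sort(tab$xUm[tab$type == "ch2"])
  expect_equal(x2 - x1, rep(0.8, 10))
})

test_that("lambda stack is the stated linear mixture", {
  g <- matrix(2, 6, 6)
  a <- matrix(0, 6, 6)
  sl <- makeLambdaStack(g, a, noiseSd = 0)
  ## single component: every pixel spectrum proportional to the GFP profile
  pw <- profileWeights(gfpEmissionProfile())
  for (b in 1:9)
    expect_equal(intensities(sl$stack)[, , b], 2 * pw[b] * matrix(1, 6, 6))
  short <- SpectralProfile(rep(1, 5), wavelengthsNm = seq(500, 540, 10))
  expect_error(makeLambdaStack(g, a, gfpProfile = short), "band mismatch")
})

test_that("movie ground truth encodes class, direction, and displacement", {
  ## zero-velocity vesicle is stationary
  mv <- makeMovie(simMovieSpec(frames = 50L,
                               vesicles = vesicleSpec(40, 0),
                               stationaryN = 0L, noiseSd = 0))
  expect_equal(mv$truth$class, "stationary")
  ## leftward vesicle is retrograde (anterior is to the left)
  mv <- makeMovie(simMovieSpec(frames = 50L,
                               vesicles = vesicleSpec(60, -1.5, 0, 0, 0),
                               stationaryN = 0L, noiseSd = 0))
  expect_equal(mv$truth$direction, "retrograde")
  ## +1.0 um/s at 0.16 um/px and 3.1 fps: 2.02 px displacement per frame
  mv <- makeMovie(simMovieSpec(frames = 50L,
                               vesicles = vesicleSpec(10, 1.0, 0, 0, 0),
                               stationaryN = 0L, noiseSd = 0))
  stepPx <- diff(mv$truth$trajectoriesUm[, 1]) / 0.16
  expect_equal(mean(stepPx), 1.0 / (0.16 * 3.1), tolerance = 1e-10)
})

test_that("bleached region has reduced background", {
  mv <- makeMovie(simMovieSpec(frames = 10L, vesicles = vesicleSpec(40, 0),
                               stationaryN = 0L, noiseSd = 0,
                               bleachedIntervalUm = c(20, 60)))
  f <- intensities(mv$movie)[, , 1]
  colUm <- (seq_len(ncol(f)) - 0.5) * 0.16
  outside <- f[1, colUm < 18]
  inside <- f[1, colUm > 22 & colUm < 38]   # away from the vesicle at 40 um
  expect_true(all(outside == 10))
  expect_true(all(inside == 2))
})
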