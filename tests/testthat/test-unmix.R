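test_that("spectral profiles validate and normalize", {
  p <- SpectralProfile(rep(2, 9))
  expect_equal(sum(profileWeights(p)), 1)
  expect_error(SpectralProfile(rep(0, 9)), "positive sum")
  expect_error(SpectralProfile(c(-1, rep(1, 8))), "non-negative")
  expect_equal(sum(profileWeights(gfpEmissionProfile())), 1)
  expect_equal(sum(profileWeights(autofluorescenceProfile())), 1)
})

test_that("reference profile is the normalized mean spectrum of the mask", {
  ## constant-spectrum stack: profile equals that spectrum
  p <- profileWeights(autofluorescenceProfile())
  d <- array(0, c(6, 6, 9))
  for (b in 1:9) d[, , b] <- 3 * p[b]
  stack <- LambdaStack(d)
  mask <- matrix(TRUE, 6, 6)
  prof <- buildReferenceProfile(stack, mask)
  expect_equal(profileWeights(prof), p, tolerance = 1e-12)
  expect_equal(sum(profileWeights(prof)), 1)
  expect_error(buildReferenceProfile(stack, matrix(FALSE, 6, 6)),
               "insufficient pixels")
  ## auto-only simulated stack recovers the simulation's profile
  sl <- makeLambdaStack(matrix(0, 5, 5), matrix(2, 5, 5), noiseSd = 0)
  prof2 <- buildReferenceProfile(sl$stack, matrix(TRUE, 5, 5))
  expect_equal(profileWeights(prof2), p, tolerance = 1e-12)
})

test_that("noise-free two-component mixtures unmix exactly", {
  g <- matrix(0.7, 4, 4); a <- matrix(0.3, 4, 4)
  sl <- makeLambdaStack(g, a, noiseSd = 0)
  u <- unmix(sl$stack)
  expect_equal(intensities(u$gfpAbundance), g, tolerance = 1e-12)
  expect_equal(intensities(u$autoAbundance), a, tolerance = 1e-12)
  expect_lt(max(intensities(u$residual)), 1e-9)

  ## pure autofluorescent pixels have zero GFP abundance
  sl2 <- makeLambdaStack(matrix(0, 4, 4), matrix(1, 4, 4), noiseSd = 0)
  u2 <- unmix(sl2$stack)
  expect_equal(max(intensities(u2$gfpAbundance)), 0)
  expect_equal(gfpOnlyImage(sl2$stack)@data, matrix(0, 4, 4))

  ## all-zero pixel -> (0, 0) with zero residual
  sl3 <- makeLambdaStack(matrix(0, 2, 2), matrix(0, 2, 2), noiseSd = 0)
  u3 <- unmix(sl3$stack)
  expect_equal(max(abs(intensities(u3$gfpAbundance))), 0)
  expect_equal(max(abs(intensities(u3$autoAbundance))), 0)
  expect_equal(max(intensities(u3$residual)), 0)
})

test_that("collinear reference profiles are rejected", {
  p <- gfpEmissionProfile()
  expect_error(unmix(makeLambdaStack(matrix(1, 3, 3), matrix(0, 3, 3),
                                     noiseSd = 0)$stack, p, p),
               "degenerate basis")
})

test_that("NNLS solution matches a grid-search oracle and pracma::lsqnonneg", {
  skip_if_not_installed("pracma")
  g <- profileWeights(gfpEmissionProfile())
  a <- profileWeights(autofluorescenceProfile())
  set.seed(21)
  ## random spectra, including ones that force a zero coefficient
  specs <- rbind(
    t(replicate(5, runif(1, 0, 2) * g + runif(1, 0, 2) * a +
                   runif(9, 0, 0.02))),
    t(replicate(5, pmax(runif(1, 0.5, 2) * g - runif(1, 0.2, 0.6) * a, 0))))
  d <- array(t(specs), c(9, 10, 1))
  d <- aperm(d, c(2, 3, 1))   # 10 x 1 x 9 stack
  u <- unmix(LambdaStack(d))
  for (i in 1:10) {
    s <- specs[i, ]
    ## oracle 1: exhaustive grid search over (a, b)
    grid <- seq(0, 3, by = 0.002)
    r2 <- function(ca, cb) sum((s - ca * g - cb * a)^2)
    bestG <- 0; bestA <- 0; best <- r2(0, 0)
    for (ca in grid) {
      ## inner minimum over cb is quadratic: solve directly then snap to grid
      cb <- max(0, sum((s - ca * g) * a) / sum(a * a))
      v <- r2(ca, cb)
      if (v < best) { best <- v; bestG <- ca; bestA <- cb }
    }
    expect_equal(intensities(u$gfpAbundance)[i, 1], bestG, tolerance = 0.005)
    expect_equal(intensities(u$autoAbundance)[i, 1], bestA, tolerance = 0.01)
    ## oracle 2: reference NNLS implementation
    nn <- pracma::lsqnonneg(cbind(g, a), s)
    expect_equal(intensities(u$gfpAbundance)[i, 1], nn$x[1], tolerance = 1e-8)
    expect_equal(intensities(u$autoAbundance)[i, 1], nn$x[2], tolerance = 1e-8)
  }
})

test_that("abundance errors match first-order noise propagation", {
  ## the per-pixel LS coefficient error has sd = noise_sd * sqrt((M^-1)_11)
  ## with M the Gram matrix of the two reference profiles; the estimator
  ## should reach that floor and not exceed it
  set.seed(31)
  g <- matrix(runif(1024, 0.2, 1), 32, 32)
  a <- matrix(runif(1024, 0.2, 1), 32, 32)
  noiseSd <- 0.01
  sl <- makeLambdaStack(g, a, noiseSd = noiseSd, seed = 8L)
  u <- unmix(sl$stack)
  err <- abs(intensities(u$gfpAbundance) - g)
  pw <- profileWeights(gfpEmissionProfile())
  aw <- profileWeights(autofluorescenceProfile())
  M <- matrix(c(sum(pw^2), sum(pw * aw), sum(pw * aw), sum(aw^2)), 2)
  sigma <- noiseSd * sqrt(solve(M)[1, 1])
  p99 <- unname(quantile(err, 0.99))
  expect_lt(p99, 3.2 * sigma)     # 99th percentile of |N(0, sigma)| = 2.58 sigma
  expect_gt(p99, 1.8 * sigma)
  expect_lt(mean(err), 2 * sigma)
})

test_that("classify mode zeroes autofluorescent pixels", {
  g <- matrix(0, 4, 4); g[, 1:2] <- 1
  a <- matrix(0, 4, 4); a[, 3:4] <- 1
  sl <- makeLambdaStack(g, a, noiseSd = 0)
  u <- unmix(sl$stack, mode = "classify")
  gfp <- intensities(u$gfpAbundance)
  expect_true(all(gfp[, 3:4] == 0))
  expect_true(all(gfp[, 1:2] > 0))
})
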