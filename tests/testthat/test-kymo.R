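## small helper: build a TimeLapse with one spot per frame at given columns
spotMovie <- function(cols, nr = 9, nc = 60, amp = 100, bg = 1) {
  d <- array(bg, c(nr, nc, length(cols)))
  for (t in seq_along(cols)) d[5, cols[t], t] <- amp
  TimeLapse(d, frameRateHz = 3.1, pixelSizeUm = 0.16)
}

test_that("kymograph geometry: static spots are vertical, moving spots sloped", {
  mv <- spotMovie(rep(20, 10))
  k <- intensities(buildKymograph(mv))
  expect_equal(dim(k), c(10L, 60L))
  expect_true(all(apply(k, 1, which.max) == 20))

  mv2 <- spotMovie(seq(5, 23, by = 2))   # +2 px/frame
  k2 <- intensities(buildKymograph(mv2))
  expect_equal(diff(apply(k2, 1, which.max)), rep(2, 9))

  ## widthPx = 1 samples the line directly: a spot off the line vanishes
  d <- array(1, c(9, 30, 3)); d[2, 10, ] <- 50
  mv3 <- TimeLapse(d)
  expect_equal(max(intensities(buildKymograph(mv3, roiRow = 5, widthPx = 1))), 1)
  expect_equal(max(intensities(buildKymograph(mv3))), 50)
  expect_error(buildKymograph(mv3, roiRow = 99), "outside image bounds")
})

test_that("detection and linking recover noise-free simulated vesicles", {
  mv <- makeMovie(simMovieSpec(
    frames = 80L,
    vesicles = rbind(vesicleSpec(10, 1.0, 0, 0, 0), vesicleSpec(70, -1.0, 0, 0, 0)),
    stationaryN = 0L, noiseSd = 0))
  tracks <- detectAndLink(buildKymograph(mv$movie))
  expect_length(tracks, 2L)
  ## positions within 1 px of the true trajectory
  for (tr in tracks) {
    xs <- tr@xPx * 0.16
    truthCols <- mv$truth$trajectoriesUm
    errs <- apply(abs(outer(xs, truthCols[tr@frames, 1], "-")), 1, min)
    err2 <- abs(xs - truthCols[tr@frames, if (xs[1] < 30) 1 else 2])
    expect_lt(max(err2), 0.16 * 1.01)
  }
  ## empty movie yields an empty track list
  empty <- TimeLapse(array(1, c(5, 30, 6)))
  expect_length(detectAndLink(buildKymograph(empty)), 0L)
})

test_that("crossing trajectories keep both tracks and are flagged", {
  ## two lines crossing mid-movie on a synthetic kymograph
  n <- 21
  k <- matrix(0, n, 60)
  for (t in 1:n) {
    k[t, 10 + 2 * (t - 1)] <- 100          # rightward
    k[t, 50 - 2 * (t - 1)] <- 80           # leftward
  }
  kymo <- new("Kymograph", data = k, pixelSizeUm = 0.16,
              frameIntervalS = 1 / 3.1, anteriorLeft = TRUE)
  tracks <- detectAndLink(kymo, threshold = 10)
  expect_gte(length(tracks), 2L)
  total <- sum(vapply(tracks, function(t) length(t@frames), 0L))
  expect_gte(total, 2L * n - 4L)   # nearly all points retained
  expect_true(any(vapply(tracks, function(t) "ambiguous-link" %in% t@flags,
                         TRUE)))
})

test_that("track classification follows the transport criteria", {
  stat <- classifyTrack(Track(1:5, c(10, 10, 10, 10, 10)))
  expect_equal(trackClass(stat), "stationary")
  expect_equal(trackDirection(stat), "none")

  mob <- classifyTrack(Track(1:4, c(10, 13, 16, 19)))
  expect_equal(trackClass(mob), "mobile")
  expect_equal(trackDirection(mob), "anterograde")

  ## too short to progress 3 px or dwell > 3 frames -> excluded
  exc <- classifyTrack(Track(1:3, c(10, 11, 12)))
  expect_equal(trackClass(exc), "excluded")

  ## slow but persistent same-direction drift accumulates to mobility
  slow <- classifyTrack(Track(1:6, c(10, 11, 12, 13, 14, 15)))
  expect_equal(trackClass(slow), "mobile")

  ## leftward = anterior = retrograde
  retro <- classifyTrack(Track(1:4, c(19, 16, 13, 10)))
  expect_equal(trackDirection(retro), "retrograde")

  ## length-1 track is excluded with a reason
  one <- classifyTrack(Track(1L, 10))
  expect_equal(trackClass(one), "excluded")
  expect_true("too-short" %in% one@flags)

  ## every track lands in exactly one class
  set.seed(4)
  for (i in 1:25) {
    x <- cumsum(c(20, sample(-4:4, 12, replace = TRUE)))
    cl <- trackClass(classifyTrack(Track(seq_along(x), x)))
    expect_true(cl %in% c("mobile", "stationary", "excluded"))
  }
})

test_that("run segmentation splits at pauses and reversals", {
  ## hand-worked example: +6 px, 4-frame pause, -6 px at 0.16 um/px
  tr <- Track(1:8, c(0, 3, 6, 6, 6, 6, 3, 0), pixelSizeUm = 0.16)
  runs <- segmentRuns(tr)
  expect_equal(nrow(runs), 2L)
  expect_equal(runs$displacementPx, c(6, -6))
  expect_equal(runs$runLengthUm, c(0.96, 0.96))
  expect_equal(runs$direction, c("anterograde", "retrograde"))

  ## monotone track: exactly one event spanning the movie
  mono <- Track(1:6, c(0, 2, 4, 6, 8, 10), pixelSizeUm = 0.16)
  runsM <- segmentRuns(mono)
  expect_equal(nrow(runsM), 1L)
  expect_equal(runsM$startFrame, 1L)
  expect_equal(runsM$endFrame, 6L)

  ## total event displacement never exceeds the path length
  set.seed(6)
  for (i in 1:20) {
    x <- cumsum(c(30, sample(c(-5:-1, 1:5), 15, replace = TRUE)))
    r <- segmentRuns(Track(seq_along(x), x))
    expect_lte(sum(abs(r$displacementPx)), sum(abs(diff(x))))
  }

  ## stationary track has no events
  expect_equal(nrow(segmentRuns(Track(1:5, rep(3, 5)))), 0L)
})

test_that("track velocity matches the constant-speed closed form", {
  ## 2 px/frame at 0.16 um/px and 3.1 fps -> 0.992 um/s
  tr <- Track(1:10, seq(0, 18, by = 2), pixelSizeUm = 0.16, frameRateHz = 3.1)
  expect_equal(trackVelocity(tr), 2 * 0.16 * 3.1, tolerance = 1e-12)
  expect_warning(v <- trackVelocity(Track(1:5, rep(3, 5))), "undefined")
  expect_true(is.na(v))
})

test_that("simulated vesicle velocity is recovered through the full chain", {
  mv <- makeMovie(simMovieSpec(
    frames = 120L, vesicles = vesicleSpec(10, 1.2, 0.05, 8L, 0),
    stationaryN = 0L, noiseSd = 0.5, seed = 5L))
  tracks <- lapply(detectAndLink(buildKymograph(mv$movie)), classifyTrack)
  lens <- vapply(tracks, function(t) length(t@frames), 0L)
  main <- tracks[[which.max(lens)]]
  expect_equal(trackClass(main), "mobile")
  expect_equal(trackDirection(main), "anterograde")
  expect_lt(abs(main@meanVelocityUmPerS - 1.2) / 1.2, 0.05)
})

test_that("transport summary computes flux and direction fractions", {
  mk <- function(x0, slope, n = 20) classifyTrack(
    Track(1:n, x0 + slope * (0:(n - 1)), pixelSizeUm = 0.16,
          frameRateHz = 3.1))
  ## 6 mobile tracks, 18 um region, 100 s -> 0.2 per um per min
  tracks <- c(lapply(seq(10, 60, by = 10), function(x0) mk(x0, 3)),
              list(classifyTrack(Track(1:20, rep(100, 20)))))
  ts <- transportSummary(tracks, 18, 100)
  expect_equal(ts$flux, 0.2)
  expect_equal(ts$nMobile, 6L)
  expect_equal(ts$nStationary, 1L)

  ## 7 anterograde + 3 retrograde -> fractions 0.7 / 0.3
  tracks2 <- c(lapply(1:7, function(i) mk(10 * i, 3)),
               lapply(1:3, function(i) mk(100 + 10 * i, -3)))
  ts2 <- transportSummary(tracks2, 18, 100)
  expect_equal(ts2$fractionAnterograde, 0.7)
  expect_equal(ts2$fractionRetrograde, 0.3)
  expect_equal(unname(ts2$velocityAnterograde["mean"]), 3 * 0.16 * 3.1)

  ## flux scales linearly with the number of mobile tracks
  ts4 <- transportSummary(c(tracks2, tracks2), 18, 100)
  expect_equal(ts4$flux, 2 * ts2$flux)

  ## no mobile tracks: zero flux, undefined fractions
  ts0 <- transportSummary(list(classifyTrack(Track(1:10, rep(5, 10)))), 18, 100)
  expect_equal(ts0$flux, 0)
  expect_true(is.na(ts0$fractionAnterograde))
  expect_error(transportSummary(tracks, 18, 0), "positive")
})

test_that("mirroring the kymograph swaps direction labels only", {
  ## noise-free and crossing-free: greedy tie-breaking is deliberately
  ## left-biased and identity swaps at crossings need not mirror
  mv <- makeMovie(simMovieSpec(
    frames = 60L,
    vesicles = rbind(vesicleSpec(10, 1.0, 0, 0, 0),
                     vesicleSpec(45, 0, 0, 0, 0),
                     vesicleSpec(70, -0.8, 0, 0, 0)),
    stationaryN = 0L, noiseSd = 0, seed = 9L))
  ky <- buildKymograph(mv$movie)
  mirrored <- new("Kymograph", data = intensities(ky)[, ncol(intensities(ky)):1],
                  pixelSizeUm = ky@pixelSizeUm,
                  frameIntervalS = ky@frameIntervalS, anteriorLeft = TRUE)
  cls <- function(k) {
    tr <- lapply(detectAndLink(k), classifyTrack)
    ord <- order(vapply(tr, function(t) t@xPx[1], 0))
    list(class = vapply(tr[ord], trackClass, ""),
         dir = vapply(tr[ord], trackDirection, ""))
  }
  a <- cls(ky); b <- cls(mirrored)
  expect_equal(sort(a$class), sort(b$class))
  swap <- c(anterograde = "retrograde", retrograde = "anterograde",
            none = "none")
  expect_equal(sort(unname(swap[a$dir])), sort(b$dir))
})
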