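#' Specification of a synthetic puncta image
#'
#' Parameters of the synthetic single-frame acquisitions: sparse
#' diffraction-limited puncta (default FWHM 0.6 um, within the 0.5-0.7 um
#' range typical of receptor clusters in ventral-cord dendrites) rendered as
#' isotropic 2D Gaussians along a horizontal nerve cord on a noisy
#' background. The default pixel size 0.16 um/px corresponds to a 100X
#' objective with an EMCCD camera, so 512 px span about 80 um of cord.
#'
#' @slot widthPx,heightPx image dimensions in pixels
#' @slot pixelSizeUm microns per pixel
#' @slot nPuncta number of puncta to render
#' @slot punctumSigmaUm Gaussian sigma of one punctum (FWHM = 2.355 sigma)
#' @slot punctumAmplitude peak amplitude above background
#' @slot backgroundLevel constant background intensity
#' @slot noiseSd standard deviation of additive Gaussian noise
#' @slot seed RNG seed; identical spec + seed reproduces the image bit-exactly
#' @export
setClass("SimImageSpec",
  representation(widthPx = "integer", heightPx = "integer",
                 pixelSizeUm = "numeric", nPuncta = "integer",
                 punctumSigmaUm = "numeric", punctumAmplitude = "numeric",
                 backgroundLevel = "numeric", noiseSd = "numeric",
                 seed = "integer"))

setValidity("SimImageSpec", function(object) {
  if (object@widthPx < 1L || object@heightPx < 1L)
    return("image dimensions must be positive")
  if (object@pixelSizeUm <= 0) return("'pixelSizeUm' must be positive")
  if (object@nPuncta < 0L) return("'nPuncta' must be non-negative")
  if (object@punctumSigmaUm <= 0) return("'punctumSigmaUm' must be positive")
  if (object@punctumAmplitude <= 0) return("'punctumAmplitude' must be positive")
  if (object@backgroundLevel < 0 || object@noiseSd < 0)
    return("background and noise must be non-negative")
  TRUE
})

#' Construct a SimImageSpec
#'
#' @param widthPx,heightPx image size in pixels (defaults 512 x 64: a strip
#'   along the cord)
#' @param pixelSizeUm microns per pixel (default 0.16)
#' @param nPuncta number of puncta (default 12)
#' @param punctumSigmaUm Gaussian sigma in um; default 0.6/2.355 so the
#'   rendered FWHM is 0.6 um
#' @param punctumAmplitude peak amplitude above background (default 100)
#' @param backgroundLevel constant background (default 10)
#' @param noiseSd additive Gaussian noise sd (default 2)
#' @param seed integer RNG seed
#' @return a \linkS4class{SimImageSpec}
#' @examples
#' spec <- simImageSpec(nPuncta = 6, noiseSd = 0)
#' sim <- makePunctaImage(spec)
#' punctaCount(detectPuncta(autoThreshold(sim$image)$mask, sim$image))
#' @export
simImageSpec <- function(widthPx = 512L, heightPx = 64L, pixelSizeUm = 0.16,
                         nPuncta = 12L, punctumSigmaUm = 0.6 / 2.355,
                         punctumAmplitude = 100, backgroundLevel = 10,
                         noiseSd = 2, seed = 1L) {
  new("SimImageSpec", widthPx = as.integer(widthPx),
      heightPx = as.integer(heightPx), pixelSizeUm = pixelSizeUm,
      nPuncta = as.integer(nPuncta), punctumSigmaUm = punctumSigmaUm,
      punctumAmplitude = punctumAmplitude, backgroundLevel = backgroundLevel,
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' Specification of a synthetic vesicle-transport movie
#'
#' Time-lapse parameters emulating spinning-disk imaging of vesicles moving
#' along an anterior region of the ventral cord: a constant frame rate of
#' 3.1 frames/s, a photobleached stretch of cord with reduced background, and
#' vesicles that move with constant speed interrupted by stochastic pauses
#' and reversals. Negative velocity means motion toward the anterior
#' (leftward), i.e. retrograde transport.
#'
#' @slot frames number of frames (2-500)
#' @slot frameRateHz frames per second
#' @slot cordLengthUm length of imaged cord in um
#' @slot vesicles data.frame, one row per mobile vesicle: startXUm,
#'   velocityUmPerS (signed), pauseProbPerFrame, pauseLenFrames,
#'   reversalProbPerFrame
#' @slot bleachedIntervalUm two-element range of the photobleached region
#' @slot stationaryN number of additional stationary vesicles
#' @slot pixelSizeUm,heightPx,punctumSigmaUm,punctumAmplitude,backgroundLevel
#'   rendering geometry, as in \linkS4class{SimImageSpec}
#' @slot bleachFactor background multiplier inside the bleached region
#' @slot noiseSd additive Gaussian noise sd
#' @slot seed RNG seed
#' @export
setClass("SimMovieSpec",
  representation(frames = "integer", frameRateHz = "numeric",
                 cordLengthUm = "numeric", vesicles = "data.frame",
                 bleachedIntervalUm = "numeric", stationaryN = "integer",
                 pixelSizeUm = "numeric", heightPx = "integer",
                 punctumSigmaUm = "numeric", punctumAmplitude = "numeric",
                 backgroundLevel = "numeric", bleachFactor = "numeric",
                 noiseSd = "numeric", seed = "integer"))

setValidity("SimMovieSpec", function(object) {
  if (object@frames < 2L || object@frames > 500L)
    return("'frames' must be between 2 and 500")
  if (object@frameRateHz <= 0) return("'frameRateHz' must be positive")
  if (object@cordLengthUm <= 0) return("'cordLengthUm' must be positive")
  need <- c("startXUm", "velocityUmPerS", "pauseProbPerFrame",
            "pauseLenFrames", "reversalProbPerFrame")
  if (!all(need %in% names(object@vesicles)))
    return(paste("vesicle table needs columns:", paste(need, collapse = ", ")))
  if (nrow(object@vesicles) &&
      (any(object@vesicles$startXUm < 0) ||
       any(object@vesicles$startXUm > object@cordLengthUm)))
    return("vesicle start position outside cord")
  if (length(object@bleachedIntervalUm) != 2L)
    return("'bleachedIntervalUm' must have length 2")
  if (object@stationaryN < 0L) return("'stationaryN' must be non-negative")
  if (object@bleachFactor < 0 || object@bleachFactor > 1)
    return("'bleachFactor' must be in [0,1]")
  TRUE
})

#' One row of a vesicle table
#'
#' @param startXUm start position along the cord (um)
#' @param velocityUmPerS signed speed; negative = anterior-directed
#'   (retrograde)
#' @param pauseProbPerFrame per-frame probability of entering a pause
#' @param pauseLenFrames pause duration in frames
#' @param reversalProbPerFrame per-frame probability of flipping direction
#' @return one-row data.frame suitable for \code{\link{simMovieSpec}}
#' @export
vesicleSpec <- function(startXUm, velocityUmPerS, pauseProbPerFrame = 0.05,
                        pauseLenFrames = 8L, reversalProbPerFrame = 0.01) {
  data.frame(startXUm = startXUm, velocityUmPerS = velocityUmPerS,
             pauseProbPerFrame = pauseProbPerFrame,
             pauseLenFrames = as.integer(pauseLenFrames),
             reversalProbPerFrame = reversalProbPerFrame)
}

#' Construct a SimMovieSpec
#'
#' Defaults emulate the acquisitions the package targets: 3.1 frames/s, an
#' ~80 um cord (512 px at 0.16 um/px), a photobleached central region at 20%
#' background, two mobile vesicles (one anterograde at +1.0 um/s, one
#' retrograde at -1.0 um/s) and three stationary puncta.
#'
#' @param frames number of frames (default 150; at most 500)
#' @param frameRateHz frames per second (default 3.1)
#' @param cordLengthUm cord length in um (default 81.92 = 512 px)
#' @param vesicles vesicle table, see \code{\link{vesicleSpec}}
#' @param bleachedIntervalUm photobleached region (default c(10, 70))
#' @param stationaryN number of stationary vesicles (default 3)
#' @param pixelSizeUm microns per pixel (default 0.16)
#' @param heightPx frame height in pixels (default 16; the cord is a line)
#' @param punctumSigmaUm vesicle spot sigma (default FWHM 0.6 um)
#' @param punctumAmplitude spot peak amplitude (default 100)
#' @param backgroundLevel unbleached background (default 10)
#' @param bleachFactor background multiplier in the bleached region
#'   (default 0.2)
#' @param noiseSd additive Gaussian noise sd (default 1)
#' @param seed integer RNG seed
#' @return a \linkS4class{SimMovieSpec}
#' @export
simMovieSpec <- function(frames = 150L, frameRateHz = 3.1,
                         cordLengthUm = 512 * 0.16,
                         vesicles = rbind(vesicleSpec(15, 1.0),
                                          vesicleSpec(65, -1.0)),
                         bleachedIntervalUm = c(10, 70), stationaryN = 3L,
                         pixelSizeUm = 0.16, heightPx = 16L,
                         punctumSigmaUm = 0.6 / 2.355,
                         punctumAmplitude = 100, backgroundLevel = 10,
                         bleachFactor = 0.2, noiseSd = 1, seed = 1L) {
  new("SimMovieSpec", frames = as.integer(frames), frameRateHz = frameRateHz,
      cordLengthUm = cordLengthUm, vesicles = vesicles,
      bleachedIntervalUm = as.numeric(bleachedIntervalUm),
      stationaryN = as.integer(stationaryN), pixelSizeUm = pixelSizeUm,
      heightPx = as.integer(heightPx), punctumSigmaUm = punctumSigmaUm,
      punctumAmplitude = punctumAmplitude, backgroundLevel = backgroundLevel,
      bleachFactor = bleachFactor, noiseSd = noiseSd, seed = as.integer(seed))
}

## Render isotropic Gaussian spots at pixel centres. Pixel (i,j) (1-based)
## has centre ((j-0.5)*s, (i-0.5)*s) um. The Gaussian is evaluated at pixel
## centres (no integration over pixel area).
renderSpots <- function(widthPx, heightPx, pixelSizeUm, xUm, yUm, amplitude,
                        sigmaUm, background = 0) {
  img <- matrix(background, heightPx, widthPx)
  if (length(xUm) == 0L) return(img)
  amplitude <- rep_len(amplitude, length(xUm))
  halfwin <- ceiling(5 * sigmaUm / pixelSizeUm)
  for (k in seq_along(xUm)) {
    jc <- xUm[k] / pixelSizeUm + 0.5   # fractional column index of the centre
    ic <- yUm[k] / pixelSizeUm + 0.5
    jj <- max(1L, floor(jc - halfwin)):min(widthPx, ceiling(jc + halfwin))
    ii <- max(1L, floor(ic - halfwin)):min(heightPx, ceiling(ic + halfwin))
    if (!length(jj) || !length(ii)) next
    gx <- exp(-((jj - jc) * pixelSizeUm)^2 / (2 * sigmaUm^2))
    gy <- exp(-((ii - ic) * pixelSizeUm)^2 / (2 * sigmaUm^2))
    img[ii, jj] <- img[ii, jj] + amplitude[k] * outer(gy, gx)
  }
  img
}

## Evenly spaced slots along the cord with sub-pixel jitter; guarantees the
## spots stay separated so ground truth remains recoverable.
cordSlots <- function(n, cordLengthUm, marginUm, jitterUm) {
  if (n == 0L) return(numeric(0))
  usable <- cordLengthUm - 2 * marginUm
  centres <- marginUm + (seq_len(n) - 0.5) / n * usable
  centres + stats::runif(n, -jitterUm, jitterUm)
}

#' Simulate a single-channel puncta image
#'
#' Renders \code{nPuncta} Gaussian spots along the horizontal midline of the
#' image (the nerve cord), adds a constant background and Gaussian noise, and
#' clips at zero. Ground truth records every true centroid and amplitude.
#'
#' @param spec a \linkS4class{SimImageSpec}
#' @param channel channel label for the returned image
#' @return list with elements \code{image} (\linkS4class{FluorImage}) and
#'   \code{truth} (list with \code{puncta} data.frame of id, xUm, yUm,
#'   amplitude, and \code{cordLengthUm})
#' @examples
#' sim <- makePunctaImage(simImageSpec(nPuncta = 12, noiseSd = 0))
#' nrow(sim$truth$puncta)
#' @export
makePunctaImage <- function(spec, channel = "GFP") {
  stopifnot(is(spec, "SimImageSpec"))
  validObject(spec)
  set.seed(spec@seed)
  cordLengthUm <- spec@widthPx * spec@pixelSizeUm
  marginUm <- max(4 * spec@punctumSigmaUm, 2)
  x <- cordSlots(spec@nPuncta, cordLengthUm, marginUm,
                 jitterUm = spec@pixelSizeUm / 2)
  y <- rep(spec@heightPx / 2 * spec@pixelSizeUm, length(x))
  img <- renderSpots(spec@widthPx, spec@heightPx, spec@pixelSizeUm, x, y,
                     spec@punctumAmplitude, spec@punctumSigmaUm,
                     spec@backgroundLevel)
  if (spec@noiseSd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, spec@noiseSd),
                        nrow(img), ncol(img))
  img <- pmax(img, 0)
  truth <- list(
    puncta = data.frame(id = seq_along(x), xUm = x, yUm = y,
                        amplitude = rep(spec@punctumAmplitude, length(x))),
    cordLengthUm = cordLengthUm)
  list(image = FluorImage(img, spec@pixelSizeUm, channel), truth = truth)
}

#' Simulate a two-channel image with a controlled colocalized fraction
#'
#' Each channel receives \code{nPuncta} puncta. A fraction
#' \code{colocFraction} of them sit at identical positions in both channels.
#' The remainder are channel-specific: with \code{offsetUm = 0} they occupy
#' disjoint positions; with \code{offsetUm > 0} every non-shared channel-2
#' punctum is placed \code{offsetUm} to the right of a non-shared channel-1
#' punctum, producing adjacent (non-overlapping) pairs for adjacency
#' statistics.
#'
#' @param spec a \linkS4class{SimImageSpec}; \code{nPuncta} is the per-channel
#'   count
#' @param colocFraction fraction of puncta shared by both channels, in [0,1]
#' @param offsetUm displacement of non-shared channel-2 puncta (um)
#' @return list with \code{ch1}, \code{ch2} (\linkS4class{FluorImage}) and
#'   \code{truth}: per-punctum table (id, xUm, yUm, type in
#'   \{shared, ch1, ch2\}), the applied \code{offsetUm}, \code{colocFraction},
#'   and \code{colocMask}, a logical matrix marking pixels within the FWHM of
#'   a shared punctum (the true-colocalization pixel label).
#' @export
makeTwoChannelImage <- function(spec, colocFraction, offsetUm = 0) {
  stopifnot(is(spec, "SimImageSpec"))
  validObject(spec)
  if (!is.finite(colocFraction) || colocFraction < 0 || colocFraction > 1)
    stop("'colocFraction' must be in [0, 1]")
  if (offsetUm < 0) stop("'offsetUm' must be non-negative")
  set.seed(spec@seed)
  n <- spec@nPuncta
  nShared <- round(colocFraction * n)
  nOnly <- n - nShared
  cordLengthUm <- spec@widthPx * spec@pixelSizeUm
  marginUm <- max(4 * spec@punctumSigmaUm, 2)
  nSlots <- nShared + nOnly + (if (offsetUm > 0) 0L else nOnly)
  slots <- cordSlots(nSlots, cordLengthUm, marginUm,
                     jitterUm = spec@pixelSizeUm / 2)
  slots <- slots[sample.int(length(slots))]  # decorrelate type from position
  yUm <- spec@heightPx / 2 * spec@pixelSizeUm

  xShared <- slots[seq_len(nShared)]
  x1only <- slots[nShared + seq_len(nOnly)]
  x2only <- if (offsetUm > 0) x1only + offsetUm
            else slots[nShared + nOnly + seq_len(nOnly)]

  x1 <- c(xShared, x1only)
  x2 <- c(xShared, x2only)
  mk <- function(x) {
    img <- renderSpots(spec@widthPx, spec@heightPx, spec@pixelSizeUm, x,
                       rep(yUm, length(x)), spec@punctumAmplitude,
                       spec@punctumSigmaUm, spec@backgroundLevel)
    if (spec@noiseSd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec@noiseSd),
                          nrow(img), ncol(img))
    pmax(img, 0)
  }
  ch1 <- mk(x1)
  ch2 <- mk(x2)

  sharedImg <- renderSpots(spec@widthPx, spec@heightPx, spec@pixelSizeUm,
                           xShared, rep(yUm, length(xShared)),
                           spec@punctumAmplitude, spec@punctumSigmaUm, 0)
  colocMask <- sharedImg > spec@punctumAmplitude / 2

  truth <- list(
    puncta = data.frame(
      id = seq_len(nShared + 2L * nOnly),
      xUm = c(xShared, x1only, x2only),
      yUm = yUm,
      type = rep(c("shared", "ch1", "ch2"), c(nShared, nOnly, nOnly))),
    offsetUm = offsetUm, colocFraction = colocFraction,
    colocMask = colocMask)
  list(ch1 = FluorImage(ch1, spec@pixelSizeUm, "ch1"),
       ch2 = FluorImage(ch2, spec@pixelSizeUm, "ch2"),
       truth = truth)
}

#' Simulate a lambda-scan stack from abundance maps
#'
#' Builds the per-pixel emission spectrum as
#' \code{gfp * gfpProfile + auto * autoProfile + noise}, clipped at zero.
#' Both profiles must share the stack's 9 bands.
#'
#' @param gfpAbundance,autoAbundance numeric matrices (or
#'   \linkS4class{FluorImage}) of per-pixel component abundances, same shape
#' @param gfpProfile,autoProfile \linkS4class{SpectralProfile} objects with
#'   9 bands
#' @param noiseSd additive Gaussian noise sd per band
#' @param seed RNG seed
#' @param pixelSizeUm microns per pixel
#' @return list with \code{stack} (\linkS4class{LambdaStack}) and
#'   \code{truth} (list with the true \code{gfp} and \code{auto} abundance
#'   matrices)
#' @export
makeLambdaStack <- function(gfpAbundance, autoAbundance,
                            gfpProfile = gfpEmissionProfile(),
                            autoProfile = autofluorescenceProfile(),
                            noiseSd = 0, seed = 1L, pixelSizeUm = 0.16) {
  g <- if (is(gfpAbundance, "FluorImage")) intensities(gfpAbundance) else as.matrix(gfpAbundance)
  a <- if (is(autoAbundance, "FluorImage")) intensities(autoAbundance) else as.matrix(autoAbundance)
  if (!identical(dim(g), dim(a)))
    stop("abundance maps must have identical dimensions")
  pw <- profileWeights(gfpProfile)
  aw <- profileWeights(autoProfile)
  if (length(pw) != 9L || length(aw) != 9L)
    stop("band mismatch: spectral profiles must have 9 bands")
  if (!isTRUE(all.equal(wavelengths(gfpProfile), wavelengths(autoProfile))))
    stop("band mismatch: profiles sampled at different wavelengths")
  set.seed(as.integer(seed))
  d <- c(dim(g), 9L)
  stack <- array(0, d)
  for (b in seq_len(9L)) stack[, , b] <- g * pw[b] + a * aw[b]
  if (noiseSd > 0) stack <- stack + array(stats::rnorm(prod(d), 0, noiseSd), d)
  stack <- pmax(stack, 0)
  list(stack = LambdaStack(stack, wavelengths(gfpProfile), pixelSizeUm),
       truth = list(gfp = g, auto = a))
}

## Simulate one vesicle trajectory frame by frame. Order of stochastic events
## within a step: reversal draw, then pause draw, then motion; a vesicle that
## reaches the cord end holds position there.
simulateTrajectory <- function(startXUm, v, pauseProb, pauseLen, revProb,
                               frames, fps, cordLengthUm) {
  x <- numeric(frames)
  x[1] <- startXUm
  pauseLeft <- 0L
  events <- list()
  for (t in 2:frames) {
    if (pauseLeft > 0L) {
      x[t] <- x[t - 1]
      pauseLeft <- pauseLeft - 1L
      next
    }
    if (v != 0 && stats::runif(1) < revProb) {
      v <- -v
      events[[length(events) + 1L]] <- data.frame(frame = t, type = "reversal")
    }
    if (v != 0 && stats::runif(1) < pauseProb) {
      pauseLeft <- as.integer(pauseLen)
      events[[length(events) + 1L]] <- data.frame(frame = t, type = "pause")
      x[t] <- x[t - 1]
      next
    }
    x[t] <- min(max(x[t - 1] + v / fps, 0), cordLengthUm)
  }
  list(xUm = x, events = if (length(events)) do.call(rbind, events)
                         else data.frame(frame = integer(0), type = character(0)))
}

#' Simulate a vesicle-transport time lapse
#'
#' Vesicles are rendered as Gaussian spots moving along the cord midline
#' according to their simulated trajectories; pauses hold position, reversals
#' flip the velocity sign, and the photobleached interval has its background
#' scaled by \code{bleachFactor}. Ground truth records the full trajectory,
#' class and direction of every vesicle.
#'
#' @param spec a \linkS4class{SimMovieSpec}
#' @return list with \code{movie} (\linkS4class{TimeLapse}) and \code{truth}:
#'   \code{trajectoriesUm} (frames x vesicles matrix, stationary vesicles
#'   included as constant columns), \code{class} ("mobile"/"stationary"),
#'   \code{direction} ("anterograde"/"retrograde"/"none"), \code{events}
#'   (per-vesicle pause/reversal log)
#' @examples
#' sim <- makeMovie(simMovieSpec(frames = 20, noiseSd = 0))
#' sim$truth$direction
#' @export
makeMovie <- function(spec) {
  stopifnot(is(spec, "SimMovieSpec"))
  validObject(spec)
  set.seed(spec@seed)
  widthPx <- round(spec@cordLengthUm / spec@pixelSizeUm)
  vt <- spec@vesicles
  nMob <- nrow(vt)

  traj <- matrix(0, spec@frames, 0)
  events <- list()
  for (k in seq_len(nMob)) {
    s <- simulateTrajectory(vt$startXUm[k], vt$velocityUmPerS[k],
                            vt$pauseProbPerFrame[k], vt$pauseLenFrames[k],
                            vt$reversalProbPerFrame[k], spec@frames,
                            spec@frameRateHz, spec@cordLengthUm)
    traj <- cbind(traj, s$xUm)
    events[[k]] <- s$events
  }
  if (spec@stationaryN > 0L) {
    margin <- max(4 * spec@punctumSigmaUm, 2)
    xs <- stats::runif(spec@stationaryN, margin, spec@cordLengthUm - margin)
    traj <- cbind(traj, matrix(rep(xs, each = spec@frames), spec@frames))
  }
  nVes <- ncol(traj)

  yUm <- spec@heightPx / 2 * spec@pixelSizeUm
  bg <- matrix(spec@backgroundLevel, spec@heightPx, widthPx)
  xCentres <- (seq_len(widthPx) - 0.5) * spec@pixelSizeUm
  inBleach <- xCentres >= spec@bleachedIntervalUm[1] &
              xCentres <= spec@bleachedIntervalUm[2]
  bg[, inBleach] <- bg[, inBleach] * spec@bleachFactor

  frames <- array(0, c(spec@heightPx, widthPx, spec@frames))
  for (t in seq_len(spec@frames)) {
    f <- renderSpots(widthPx, spec@heightPx, spec@pixelSizeUm,
                     traj[t, ], rep(yUm, nVes), spec@punctumAmplitude,
                     spec@punctumSigmaUm, 0) + bg
    if (spec@noiseSd > 0)
      f <- f + matrix(stats::rnorm(length(f), 0, spec@noiseSd),
                      spec@heightPx, widthPx)
    frames[, , t] <- pmax(f, 0)
  }

  vClass <- c(ifelse(vt$velocityUmPerS == 0, "stationary", "mobile"),
              rep("stationary", spec@stationaryN))
  vDir <- c(ifelse(vt$velocityUmPerS < 0, "retrograde",
                   ifelse(vt$velocityUmPerS > 0, "anterograde", "none")),
            rep("none", spec@stationaryN))
  list(movie = TimeLapse(frames, spec@frameRateHz, spec@pixelSizeUm),
       truth = list(trajectoriesUm = traj, class = vClass, direction = vDir,
                    events = events))
}
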