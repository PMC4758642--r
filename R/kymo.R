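#' Build a kymograph from a time lapse
#'
#' Collapses each frame onto the line ROI along the cord: row t of the
#' kymograph holds, for every position along the ROI, the maximum intensity
#' across the averaging width centred on the ROI row. Rows are frames (time
#' downward), columns are positions; the anterior of the animal (the
#' retrograde direction) is at the left.
#'
#' @param movie a \linkS4class{TimeLapse}
#' @param roiRow image row of the line ROI (default: the middle row)
#' @param widthPx averaging width in pixels; \code{widthPx = 1} reduces to
#'   plain sampling along the line (default: the full frame height)
#' @return a \linkS4class{Kymograph}
#' @export
buildKymograph <- function(movie, roiRow = NULL, widthPx = NULL) {
  d <- intensities(movie)
  nr <- dim(d)[1]; nc <- dim(d)[2]; nf <- dim(d)[3]
  if (is.null(roiRow)) roiRow <- ceiling(nr / 2)
  if (is.null(widthPx)) widthPx <- nr
  if (roiRow < 1L || roiRow > nr) stop("ROI row outside image bounds")
  half <- (widthPx - 1) %/% 2
  rows <- max(1L, roiRow - half):min(nr, roiRow + half + (widthPx - 1) %% 2)
  k <- matrix(0, nf, nc)
  for (t in seq_len(nf)) {
    sub <- d[rows, , t, drop = FALSE]
    k[t, ] <- apply(sub, 2, max)
  }
  new("Kymograph", data = k, pixelSizeUm = pixelSize(movie),
      frameIntervalS = 1 / frameRate(movie), anteriorLeft = TRUE)
}

## local maxima of one kymograph row above a threshold; plateaus of equal
## values collapse to their centre column
rowMaxima <- function(v, threshold) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  cand <- which(v > threshold)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[v[cand] >= v[cand - 1L] & v[cand] >= v[cand + 1L]]
  if (!length(cand)) return(integer(0))
  # collapse adjacent candidates (plateaus) to their centre
  grp <- cumsum(c(1L, diff(cand) > 1L))
  as.integer(round(tapply(cand, grp, function(i) mean(range(i)))))
}

#' Detect and link particles on a kymograph
#'
#' Per-row local maxima above \code{threshold} are linked greedily to the
#' nearest maximum in the next row within \code{maxLinkPx}; unlinked maxima
#' start new tracks. When two tracks compete for the same maximum (e.g. at a
#' crossing) the nearer track wins, ties break toward the smaller column
#' index, and both tracks are flagged \code{"ambiguous-link"} — crossing
#' trajectories may swap identity there.
#'
#' @param kymo a \linkS4class{Kymograph}
#' @param threshold detection threshold; default: Otsu on the kymograph
#' @param maxLinkPx maximum per-frame jump in pixels (default 6; must be at
#'   least 3 so linking never precludes the mobility criterion)
#' @param minLenFrames discard tracks shorter than this many frames
#'   (default 5)
#' @return list of \linkS4class{Track} (unclassified; see
#'   \code{\link{classifyTrack}})
#' @export
detectAndLink <- function(kymo, threshold = NULL, maxLinkPx = 6L,
                          minLenFrames = 5L) {
  if (maxLinkPx < 3L) stop("'maxLinkPx' must be >= 3")
  k <- intensities(kymo)
  if (is.null(threshold)) {
    threshold <- if (max(k) > min(k)) autoThreshold(k)$threshold else Inf
  }
  nf <- nrow(k)
  peaks <- lapply(seq_len(nf), function(t) rowMaxima(k[t, ], threshold))
  active <- list()   # each: list(frames, x, flagged)
  done <- list()
  for (t in seq_len(nf)) {
    p <- peaks[[t]]
    claimed <- rep(FALSE, length(p))
    if (length(active)) {
      # greedy: process tracks in order of their current position
      ord <- order(vapply(active, function(tr) tr$x[length(tr$x)], 0))
      keep <- rep(TRUE, length(active))
      for (i in ord) {
        tr <- active[[i]]
        cur <- tr$x[length(tr$x)]
        if (!length(p)) { keep[i] <- FALSE; done <- c(done, list(tr)); next }
        dist <- abs(p - cur)
        dist[claimed] <- Inf
        j <- which(dist == min(dist))
        if (length(j) > 1L) {            # equidistant candidates: take the
          j <- j[which.min(p[j])]        # smaller column, flag the ambiguity
          tr$flagged <- TRUE
        }
        if (dist[j] <= maxLinkPx) {
          claimed[j] <- TRUE
          tr$frames <- c(tr$frames, t)
          tr$x <- c(tr$x, p[j])
          active[[i]] <- tr
        } else {
          keep[i] <- FALSE
          done <- c(done, list(tr))
        }
      }
      # flag tracks whose claimed peak was also the nearest unclaimed-at-the-
      # time peak of another surviving track (identity may have swapped)
      if (sum(keep) > 1L) {
        tails <- vapply(active[keep], function(tr) tr$x[length(tr$x)], 0)
        o <- order(tails)
        close <- which(diff(sort(tails)) <= maxLinkPx)
        if (length(close)) {
          ik <- which(keep)[o]
          for (ci in close) {
            active[[ik[ci]]]$flagged <- TRUE
            active[[ik[ci + 1L]]]$flagged <- TRUE
          }
        }
      }
      active <- active[keep]
    }
    # unclaimed maxima start new tracks
    for (j in which(!claimed))
      active[[length(active) + 1L]] <- list(frames = t, x = p[j],
                                            flagged = FALSE)
  }
  done <- c(done, active)
  done <- Filter(function(tr) length(tr$frames) >= minLenFrames, done)
  lapply(done, function(tr)
    Track(tr$frames, tr$x, pixelSizeUm = kymo@pixelSizeUm,
          frameRateHz = 1 / kymo@frameIntervalS,
          flags = if (isTRUE(tr$flagged)) "ambiguous-link" else character(0)))
}

## steps of a track: per-frame displacements (assumes consecutive frames)
trackSteps <- function(t) diff(t@xPx)

## maximal stretches of successive non-pause steps with constant sign;
## returns data.frame(startStep, endStep, sumDx)
signSpells <- function(dx, pausePx = 1) {
  s <- ifelse(abs(dx) < pausePx, 0L, sign(dx))
  out <- list()
  i <- 1L
  n <- length(s)
  while (i <= n) {
    if (s[i] == 0L) { i <- i + 1L; next }
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    out[[length(out) + 1L]] <- data.frame(startStep = i, endStep = j,
                                          sumDx = sum(dx[i:j]))
    i <- j + 1L
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(startStep = integer(0), endStep = integer(0),
                  sumDx = numeric(0))
}

#' Classify a track as mobile, stationary or excluded
#'
#' Transport criteria: a particle is \emph{mobile} when its displacement
#' accumulated over successive same-direction frames reaches \code{movePx}
#' pixels (a single step of \code{movePx} is the limiting case);
#' \emph{stationary} when it stays immobile (per-frame displacement below
#' \code{movePx}) for more than \code{stationaryFrames} consecutive frames
#' without ever qualifying as mobile; anything else — short tracks, slow
#' drift that neither progresses nor dwells — is \emph{excluded}. Direction
#' comes from the sign of the net displacement: decreasing x is anterior,
#' i.e. retrograde; zero net displacement gives direction "none".
#'
#' @param t a \linkS4class{Track}
#' @param movePx mobility threshold in pixels (default 3)
#' @param stationaryFrames immobile spell length that defines a stationary
#'   particle, in frames (default 3: a spell must exceed this)
#' @param minLenFrames tracks shorter than this are excluded (default 2)
#' @return the track with \code{class}, \code{direction}, \code{runs} and
#'   \code{meanVelocityUmPerS} filled in
#' @examples
#' tr <- Track(1:4, c(10, 13, 16, 19))
#' trackClass(classifyTrack(tr))       # "mobile"
#' trackDirection(classifyTrack(tr))   # "anterograde"
#' @export
classifyTrack <- function(t, movePx = 3L, stationaryFrames = 3L,
                          minLenFrames = 2L) {
  n <- length(t@frames)
  if (n < max(2L, minLenFrames)) {
    t@classification <- "excluded"
    t@flags <- union(t@flags, "too-short")
    return(t)
  }
  dx <- trackSteps(t)
  spells <- signSpells(dx)
  mobile <- nrow(spells) > 0 && any(abs(spells$sumDx) >= movePx)
  if (mobile) {
    t@classification <- "mobile"
    net <- sum(dx)
    t@direction <- if (net > 0) "anterograde" else if (net < 0) "retrograde"
                   else "none"
    t@runs <- segmentRuns(t, movePx)
    t@meanVelocityUmPerS <- if (nrow(t@runs))
      mean(t@runs$velocityUmPerS) else NA_real_
    return(t)
  }
  # immobile spells: consecutive steps with |dx| < movePx; spell length in
  # frames is the step count + 1
  im <- abs(dx) < movePx
  r <- rle(im)
  longest <- if (any(r$values)) max(r$lengths[r$values]) + 1L else 0L
  t@classification <- if (longest > stationaryFrames) "stationary" else "excluded"
  t@direction <- "none"
  t
}

#' Segment a track into movement events (runs)
#'
#' A movement event is a maximal stretch of successive frames with constant
#' direction of motion and cumulative displacement of at least \code{movePx}
#' pixels; events are delimited by pauses (frames without displacement),
#' reversals of direction, or the end of the movie. The run length is the
#' absolute displacement of the event in microns.
#'
#' @param t a \linkS4class{Track}
#' @param movePx minimum cumulative displacement for a stretch to count as an
#'   event (default 3)
#' @param pausePx per-frame displacement below which a frame counts as a
#'   pause (default 1 px)
#' @return data.frame with one row per event: startFrame, endFrame,
#'   displacementPx (signed), runLengthUm, durationS, velocityUmPerS,
#'   direction
#' @examples
#' tr <- Track(1:8, c(0, 3, 6, 6, 6, 6, 3, 0), pixelSizeUm = 0.16)
#' segmentRuns(tr)   # two events of 0.96 um separated by a pause
#' @export
segmentRuns <- function(t, movePx = 3L, pausePx = 1) {
  dx <- trackSteps(t)
  if (!length(dx)) return(emptyRuns())
  spells <- signSpells(dx, pausePx)
  spells <- spells[abs(spells$sumDx) >= movePx, , drop = FALSE]
  if (!nrow(spells)) return(emptyRuns())
  fr <- t@frames
  data.frame(
    startFrame = fr[spells$startStep],
    endFrame = fr[spells$endStep + 1L],
    displacementPx = spells$sumDx,
    runLengthUm = abs(spells$sumDx) * t@pixelSizeUm,
    durationS = (spells$endStep - spells$startStep + 1L) / t@frameRateHz,
    velocityUmPerS = abs(spells$sumDx) * t@pixelSizeUm /
      ((spells$endStep - spells$startStep + 1L) / t@frameRateHz),
    direction = ifelse(spells$sumDx > 0, "anterograde", "retrograde"))
}

emptyRuns <- function() {
  data.frame(startFrame = integer(0), endFrame = integer(0),
             displacementPx = numeric(0), runLengthUm = numeric(0),
             durationS = numeric(0), velocityUmPerS = numeric(0),
             direction = character(0))
}

#' Mean run velocity of a mobile track
#'
#' Mean over the track's movement events of run length divided by event
#' duration (duration = number of steps / frame rate). Undefined for tracks
#' without events.
#'
#' @param t a classified, mobile \linkS4class{Track}
#' @param movePx passed to \code{\link{segmentRuns}} when runs have not been
#'   segmented yet
#' @return velocity in um/s, or NA with a warning when the track has no
#'   movement events
#' @export
trackVelocity <- function(t, movePx = 3L) {
  runs <- if (nrow(t@runs)) t@runs else segmentRuns(t, movePx)
  if (!nrow(runs)) {
    warning("track has no movement events; velocity undefined")
    return(NA_real_)
  }
  mean(runs$velocityUmPerS)
}

#' Summarize transport over a set of tracks
#'
#' Computes the flux (moving puncta per micron of cord per minute over the
#' analyzed region), the anterograde/retrograde split of directed mobile
#' tracks, per-direction velocity mean and SEM, and reversal statistics
#' reported both per track (fraction of mobile tracks with at least one
#' direction reversal) and per event.
#'
#' @param tracks list of classified \linkS4class{Track} objects
#' @param regionLengthUm length of the analyzed region in um (15-20 um in the
#'   emulated acquisitions)
#' @param durationS total movie duration in seconds
#' @param regionUm optional c(min, max) window in um; only mobile tracks
#'   intersecting it count toward the flux (default: all mobile tracks)
#' @return list of class \code{TransportSummary}
#' @export
transportSummary <- function(tracks, regionLengthUm, durationS,
                             regionUm = NULL) {
  if (regionLengthUm <= 0) stop("'regionLengthUm' must be positive")
  if (durationS <= 0) stop("'durationS' must be positive")
  cls <- vapply(tracks, trackClass, "")
  mob <- tracks[cls == "mobile"]
  if (!is.null(regionUm)) {
    inRegion <- vapply(mob, function(t) {
      x <- t@xPx * t@pixelSizeUm
      any(x >= regionUm[1] & x <= regionUm[2])
    }, TRUE)
    mobRegion <- mob[inRegion]
  } else mobRegion <- mob
  flux <- length(mobRegion) / (regionLengthUm * durationS / 60)

  dirs <- vapply(mob, trackDirection, "")
  directed <- dirs[dirs != "none"]
  fracA <- if (length(directed)) mean(directed == "anterograde") else NA_real_
  fracR <- if (length(directed)) mean(directed == "retrograde") else NA_real_

  velBy <- function(d) {
    v <- vapply(mob[dirs == d], function(t) t@meanVelocityUmPerS, 0)
    v <- v[is.finite(v)]
    if (length(v) < 1L) return(c(mean = NA_real_, sem = NA_real_, n = 0))
    c(mean = mean(v),
      sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      n = length(v))
  }
  revPerTrack <- vapply(mob, function(t)
    nrow(t@runs) > 1L && length(unique(t@runs$direction)) > 1L, TRUE)
  allRuns <- do.call(rbind, c(lapply(mob, function(t) t@runs),
                              list(emptyRuns())))
  nEvents <- nrow(allRuns)
  nReversals <- sum(vapply(mob, function(t) {
    d <- t@runs$direction
    if (length(d) < 2L) 0L else sum(d[-1] != d[-length(d)])
  }, 0L))

  structure(list(
    flux = flux, regionLengthUm = regionLengthUm, durationS = durationS,
    nMobile = length(mob), nStationary = sum(cls == "stationary"),
    nExcluded = sum(cls == "excluded"),
    fractionAnterograde = fracA, fractionRetrograde = fracR,
    velocityAnterograde = velBy("anterograde"),
    velocityRetrograde = velBy("retrograde"),
    fractionTracksReversing = if (length(mob)) mean(revPerTrack) else NA_real_,
    nEvents = nEvents, nReversals = nReversals,
    reversalsPerEvent = if (nEvents) nReversals / nEvents else NA_real_),
    class = "TransportSummary")
}

#' @export
print.TransportSummary <- function(x, ...) {
  cat(sprintf("TransportSummary: flux %.3g per um per min (%g um, %.3g s)\n",
              x$flux, x$regionLengthUm, x$durationS))
  cat(sprintf("  tracks: %d mobile / %d stationary / %d excluded\n",
              x$nMobile, x$nStationary, x$nExcluded))
  if (!is.na(x$fractionAnterograde))
    cat(sprintf("  direction: %.0f%% anterograde / %.0f%% retrograde\n",
                100 * x$fractionAnterograde, 100 * x$fractionRetrograde))
  invisible(x)
}
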