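#' Tolerance-factor pixel colocalization
#'
#' The scatter-plot colocalization estimator used for two-channel neuronal
#' images: each channel is min-max rescaled to [0, 1] over its above-threshold
#' pixels, and a pixel counts as colocalized when it is above threshold in
#' BOTH channels and the rescaled intensities agree within \code{tolerance}.
#' The fraction is normalized to the number of above-threshold channel-1
#' pixels (the GFP channel in the original workflow). Rescaling lets a single
#' tolerance apply across exposures.
#'
#' @param ch1,ch2 \linkS4class{FluorImage} or numeric matrices, same shape
#' @param mask1,mask2 logical channel masks; default: the percentile
#'   threshold retaining the brightest 5% of pixels per channel
#' @param tolerance allowed difference of rescaled intensities (default 0.1)
#' @param excludeMask optional logical matrix of pixels to drop from both
#'   masks before any statistic (e.g. autofluorescent pixels flagged by
#'   \code{\link{unmix}} or by a third-channel mask)
#' @return list of class \code{ColocResult}: \code{fraction} (NA when no
#'   channel-1 pixels survive), \code{nColocPx}, \code{nCh1Px},
#'   \code{tolerance} and \code{mask}, the binary colocalization mask
#' @examples
#' m <- matrix(runif(64, 1, 10), 8, 8)
#' r <- toleranceColoc(m, m)    # identical channels
#' r$fraction
#' @export
toleranceColoc <- function(ch1, ch2, mask1 = NULL, mask2 = NULL,
                           tolerance = 0.1, excludeMask = NULL) {
  x1 <- if (is(ch1, "FluorImage")) intensities(ch1) else as.matrix(ch1)
  x2 <- if (is(ch2, "FluorImage")) intensities(ch2) else as.matrix(ch2)
  if (!identical(dim(x1), dim(x2)))
    stop("channel images must have identical dimensions")
  if (tolerance < 0) stop("'tolerance' must be non-negative")
  if (is.null(mask1)) mask1 <- autoThreshold(x1, "percentile")$mask
  if (is.null(mask2)) mask2 <- autoThreshold(x2, "percentile")$mask
  if (!is.null(excludeMask)) {
    mask1 <- mask1 & !excludeMask
    mask2 <- mask2 & !excludeMask
  }
  rescale <- function(x, m) {
    out <- matrix(NA_real_, nrow(x), ncol(x))
    if (any(m)) {
      v <- x[m]
      rng <- range(v)
      out[m] <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else 0
    }
    out
  }
  r1 <- rescale(x1, mask1)
  r2 <- rescale(x2, mask2)
  joint <- mask1 & mask2
  colocMask <- joint & (abs(r1 - r2) <= tolerance)
  colocMask[is.na(colocMask)] <- FALSE
  n1 <- sum(mask1)
  structure(list(
    fraction = if (n1 > 0) sum(colocMask) / n1 else NA_real_,
    nColocPx = sum(colocMask), nCh1Px = n1, tolerance = tolerance,
    mask = colocMask), class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  cat(sprintf("ColocResult: %d / %d ch1 pixels colocalized (fraction %s, tolerance %g)\n",
              x$nColocPx, x$nCh1Px,
              if (is.na(x$fraction)) "undefined" else sprintf("%.3f", x$fraction),
              x$tolerance))
  invisible(x)
}

#' Pearson correlation colocalization
#'
#' Sample Pearson correlation of the two channel intensities over the pixels
#' of a joint mask, the estimator used for thresholded intestinal images. A
#' channel that is constant over the mask has no defined correlation; the
#' result is flagged rather than raising an error.
#'
#' @param ch1,ch2 \linkS4class{FluorImage} or numeric matrices, same shape
#' @param jointMask logical matrix of pixels entering the computation;
#'   default: pixels above the per-channel 5% percentile threshold in both
#'   channels
#' @param excludeMask optional logical matrix of pixels to drop (e.g.
#'   autofluorescence)
#' @return list of class \code{PearsonResult}: \code{r} (NA when undefined),
#'   \code{nPx}, \code{undefined} flag
#' @export
pearsonColoc <- function(ch1, ch2, jointMask = NULL, excludeMask = NULL) {
  x1 <- if (is(ch1, "FluorImage")) intensities(ch1) else as.matrix(ch1)
  x2 <- if (is(ch2, "FluorImage")) intensities(ch2) else as.matrix(ch2)
  if (!identical(dim(x1), dim(x2)))
    stop("channel images must have identical dimensions")
  if (is.null(jointMask))
    jointMask <- autoThreshold(x1, "percentile")$mask &
                 autoThreshold(x2, "percentile")$mask
  if (!is.null(excludeMask)) jointMask <- jointMask & !excludeMask
  n <- sum(jointMask)
  if (n < 3L) stop("need at least 3 pixels in the joint mask")
  v1 <- x1[jointMask]; v2 <- x2[jointMask]
  undef <- stats::sd(v1) == 0 || stats::sd(v2) == 0
  structure(list(r = if (undef) NA_real_ else stats::cor(v1, v2),
                 nPx = n, undefined = undef), class = "PearsonResult")
}

#' @export
print.PearsonResult <- function(x, ...) {
  cat(sprintf("PearsonResult: r = %s over %d pixels\n",
              if (x$undefined) "undefined (constant channel)"
              else sprintf("%.4f", x$r), x$nPx))
  invisible(x)
}

#' Adjacency fraction between two puncta sets
#'
#' Fraction of A-puncta whose nearest B-centroid lies within
#' \code{maxDistUm}. Captures the "adjacent but not overlapping" spatial
#' relationship (within 1 um by default) between two organelle markers.
#'
#' @param psA,psB \linkS4class{PunctaSet} objects (centroids in um)
#' @param maxDistUm adjacency radius in um (default 1)
#' @return fraction in [0, 1]; NA (with a warning) when \code{psB} is empty
#' @export
adjacencyFraction <- function(psA, psB, maxDistUm = 1) {
  a <- punctaTable(psA); b <- punctaTable(psB)
  if (nrow(a) == 0L) stop("'psA' contains no puncta")
  if (nrow(b) == 0L) {
    warning("'psB' contains no puncta; adjacency fraction undefined")
    return(NA_real_)
  }
  d2 <- outer(a$xUm, b$xUm, "-")^2 + outer(a$yUm, b$yUm, "-")^2
  nearest <- sqrt(apply(d2, 1, min))
  mean(nearest <= maxDistUm)
}
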