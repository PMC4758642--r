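#' Automatic image thresholding
#'
#' Separates fluorescent objects from background. \code{method = "otsu"}
#' maximizes the between-class variance by exhaustive search over all split
#' levels of a 256-bin intensity histogram (min-max rescaled);
#' \code{method = "percentile"} retains the brightest \code{percentile}
#' fraction of pixels, the pixel-fraction criterion used for colocalization
#' channel masks (ties broken by value, then by index).
#'
#' @param img a \linkS4class{FluorImage} or numeric matrix
#' @param method "otsu" or "percentile"
#' @param percentile fraction of pixels to retain when
#'   \code{method = "percentile"} (default 0.05)
#' @param levels number of histogram bins for the Otsu search (default 256)
#' @return list with \code{mask} (logical matrix, TRUE strictly above the
#'   threshold) and \code{threshold} (numeric, on the intensity scale of
#'   \code{img})
#' @examples
#' img <- FluorImage(matrix(c(rep(10, 50), rep(100, 50)), 10, 10))
#' autoThreshold(img)$threshold
#' @export
autoThreshold <- function(img, method = c("otsu", "percentile"),
                          percentile = 0.05, levels = 256L) {
  method <- match.arg(method)
  x <- if (is(img, "FluorImage")) intensities(img) else as.matrix(img)
  if (length(x) == 0L) stop("image is empty")
  mn <- min(x); mx <- max(x)
  if (method == "otsu") {
    if (mx == mn)
      stop("degenerate histogram: image is constant, Otsu threshold undefined")
    thr <- mn + otsuLevel((x - mn) / (mx - mn), levels) * (mx - mn)
  } else {
    if (percentile <= 0 || percentile > 1)
      stop("'percentile' must be in (0, 1]")
    k <- round(percentile * length(x))
    if (k < 1L) k <- 1L
    ord <- order(-x, seq_along(x))   # value descending, then index ascending
    keep <- ord[seq_len(k)]
    mask <- matrix(FALSE, nrow(x), ncol(x))
    mask[keep] <- TRUE
    # threshold reported as the smallest retained intensity
    return(list(mask = mask, threshold = min(x[keep])))
  }
  list(mask = x > thr, threshold = thr)
}

## Otsu threshold on [0,1]-scaled intensities: exhaustive search over all
## histogram split levels maximizing the between-class variance
## w1 * w2 * (m1 - m2)^2. Empty bins tie exactly with the preceding split;
## ties resolve to the midpoint of the first and last maximizing bins.
otsuLevel <- function(xs, levels = 256L) {
  breaks <- seq(0, 1, length.out = levels + 1L)
  h <- hist(as.vector(xs), breaks = breaks, plot = FALSE)
  counts <- as.double(h$counts)
  mids <- h$mids
  n <- sum(counts)
  w1 <- cumsum(counts)
  w2 <- n - w1
  m1sum <- cumsum(counts * mids)
  m2sum <- m1sum[levels] - m1sum
  ok <- w1 > 0 & w2 > 0
  v <- rep(NA_real_, levels)
  v[ok] <- w1[ok] * w2[ok] * (m1sum[ok] / w1[ok] - m2sum[ok] / w2[ok])^2
  best <- which(v == max(v, na.rm = TRUE))
  (mids[best[1]] + mids[best[length(best)]]) / 2
}

## connected components of a logical mask via the pixel adjacency graph
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) return(lab)
  pos <- matrix(0L, nr, nc)
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  edges <- integer(0)
  addEdges <- function(dr, dc) {
    ok <- r + dr >= 1L & r + dr <= nr & cc + dc >= 1L & cc + dc <= nc
    if (!any(ok)) return(integer(0))
    nb <- (cc[ok] + dc - 1L) * nr + (r[ok] + dr)
    hit <- mask[nb]
    if (!any(hit)) return(integer(0))
    rbind(pos[idx[ok][hit]], pos[nb[hit]])
  }
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  el <- do.call(cbind, c(lapply(shifts, function(s) addEdges(s[1], s[2])),
                         list(matrix(integer(0), 2, 0))))
  g <- igraph::graph_from_edgelist(t(el), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Detect puncta as connected components of a thresholded mask
#'
#' Connected components (4- or 8-connectivity) of \code{mask} are filtered by
#' \code{minArea} and summarized with intensity-weighted centroids, areas and
#' integrated intensities. Two spots merged into one component are reported
#' as a single punctum: detection does not split touching objects.
#'
#' @param mask logical matrix, as returned by \code{\link{autoThreshold}}
#' @param img the \linkS4class{FluorImage} the mask came from
#' @param minArea minimum component area in pixels (default 4, rejecting
#'   single-pixel noise)
#' @param connectivity 4 or 8 (default 8)
#' @param threshold threshold value to record in the result (optional)
#' @param cordLengthUm length of cord analyzed, recorded for density
#'   computations (defaults to the image width in um)
#' @return a \linkS4class{PunctaSet}
#' @export
detectPuncta <- function(mask, img, minArea = 4L, connectivity = 8L,
                         threshold = NA_real_, cordLengthUm = NULL) {
  x <- if (is(img, "FluorImage")) intensities(img) else as.matrix(img)
  ps <- if (is(img, "FluorImage")) pixelSize(img) else 1
  if (!identical(dim(mask), dim(x)))
    stop("dimension mismatch between mask and image")
  if (is.null(cordLengthUm)) cordLengthUm <- ncol(x) * ps
  lab <- labelComponents(mask, as.integer(connectivity))
  n <- max(lab)
  rows <- list()
  for (k in seq_len(n)) {
    pix <- which(lab == k)
    if (length(pix) < minArea) next
    r <- ((pix - 1L) %% nrow(x)) + 1L
    cc <- ((pix - 1L) %/% nrow(x)) + 1L
    w <- x[pix]
    tw <- sum(w)
    # intensity-weighted centroid at pixel centres, in um
    xc <- if (tw > 0) sum((cc - 0.5) * w) / tw else mean(cc - 0.5)
    yc <- if (tw > 0) sum((r - 0.5) * w) / tw else mean(r - 0.5)
    rows[[length(rows) + 1L]] <- data.frame(
      id = length(rows) + 1L, xUm = xc * ps, yUm = yc * ps,
      xPx = xc, yPx = yc, areaPx = length(pix), areaUm2 = length(pix) * ps^2,
      integratedIntensity = tw,
      xminPx = min(cc), xmaxPx = max(cc), yminPx = min(r), ymaxPx = max(r))
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), xUm = numeric(0), yUm = numeric(0),
               xPx = numeric(0), yPx = numeric(0), areaPx = integer(0),
               areaUm2 = numeric(0), integratedIntensity = numeric(0),
               xminPx = integer(0), xmaxPx = integer(0),
               yminPx = integer(0), ymaxPx = integer(0))
  new("PunctaSet", puncta = tab, threshold = threshold, pixelSizeUm = ps,
      cordLengthUm = cordLengthUm)
}

#' Puncta density per 100 um of nerve cord
#'
#' @param ps a \linkS4class{PunctaSet}
#' @param cordLengthUm length of cord analyzed (um); defaults to the value
#'   recorded in \code{ps}
#' @return puncta per 100 um: \code{count * 100 / cordLengthUm}
#' @examples
#' ## 12 puncta over 60 um of cord
#' ps <- new("PunctaSet",
#'   puncta = data.frame(id = 1:12, xUm = 1:12, yUm = 0, areaPx = 5L,
#'                       integratedIntensity = 1),
#'   pixelSizeUm = 0.16)
#' punctaDensity(ps, 60)  # 20 per 100 um
#' @export
punctaDensity <- function(ps, cordLengthUm = NULL) {
  if (is.null(cordLengthUm)) cordLengthUm <- ps@cordLengthUm
  if (!is.finite(cordLengthUm) || cordLengthUm <= 0)
    stop("'cordLengthUm' must be positive")
  punctaCount(ps) * 100 / cordLengthUm
}

#' Circular region of interest
#'
#' @param xPx,yPx centre in pixel coordinates (0-based, pixel centres at
#'   integer + 0.5)
#' @param radiusPx radius in pixels (default 50, the ROI radius used for
#'   intestinal cell measurements)
#' @return object of class \code{RoiCircle}
#' @export
roiCircle <- function(xPx, yPx, radiusPx = 50) {
  if (radiusPx <= 0) stop("'radiusPx' must be positive")
  structure(list(xPx = xPx, yPx = yPx, radiusPx = radiusPx),
            class = "RoiCircle")
}

roiMask <- function(roi, nr, nc) {
  cx <- rep((seq_len(nc) - 0.5), each = nr)
  cy <- rep((seq_len(nr) - 0.5), nc)
  matrix((cx - roi$xPx)^2 + (cy - roi$yPx)^2 <= roi$radiusPx^2, nr, nc)
}

#' Integrated fluorescence density over a region
#'
#' Sum of the detectable pixel intensities in a region: pixels at or below
#' the active threshold contribute zero. The region may be a logical mask or
#' a \code{\link{roiCircle}}.
#'
#' @param img a \linkS4class{FluorImage} or numeric matrix
#' @param region logical mask (same shape as \code{img}) or an
#'   \code{RoiCircle}
#' @param threshold detectability threshold (default 0: all positive pixels
#'   count)
#' @return the integrated density (numeric scalar)
#' @export
integratedDensity <- function(img, region, threshold = 0) {
  x <- if (is(img, "FluorImage")) intensities(img) else as.matrix(img)
  if (inherits(region, "RoiCircle")) {
    m <- roiMask(region, nrow(x), ncol(x))
    if (!any(m)) stop("region lies fully outside the image")
  } else {
    m <- region
    if (!identical(dim(m), dim(x)))
      stop("dimension mismatch between region mask and image")
  }
  v <- x[m]
  sum(v[v > threshold])
}
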