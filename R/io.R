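## TIFF I/O. Intensities are stored as 32-bit float scaled by a full-scale
## constant (default 4095: the 12-bit camera range the acquisitions fill),
## because the TIFF writer expects samples in [0, 1]. Reading multiplies the
## scale back.

fullScaleDefault <- 4095

#' Write / read a single-channel image as TIFF
#'
#' Images are written as 32-bit float TIFF with intensities divided by
#' \code{fullScale} (default 4095, a 12-bit camera range); reading restores
#' the original scale. Values above \code{fullScale} are clipped with a
#' warning.
#'
#' @param img a \linkS4class{FluorImage}
#' @param path output path
#' @param fullScale intensity corresponding to 1.0 in the file
#' @return \code{writeImageTIFF}: the path, invisibly. \code{readImageTIFF}:
#'   a \linkS4class{FluorImage}.
#' @export
writeImageTIFF <- function(img, path, fullScale = fullScaleDefault) {
  x <- intensities(img) / fullScale
  if (any(x > 1)) {
    warning("intensities above fullScale clipped on write")
    x <- pmin(x, 1)
  }
  tiff::writeTIFF(x, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname writeImageTIFF
#' @param pixelSizeUm pixel size to attach on read (not stored in the file)
#' @param channel channel label to attach on read
#' @export
readImageTIFF <- function(path, pixelSizeUm = 0.16, channel = "",
                          fullScale = fullScaleDefault) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]   # drop extra samples if present
  FluorImage(x * fullScale, pixelSizeUm, channel)
}

#' Write / read a lambda stack as multi-page TIFF
#'
#' Pages are ordered by ascending wavelength.
#'
#' @param stack a \linkS4class{LambdaStack}
#' @param path output path
#' @param fullScale intensity corresponding to 1.0 in the file
#' @return \code{writeLambdaStackTIFF}: the path, invisibly;
#'   \code{readLambdaStackTIFF}: a \linkS4class{LambdaStack}
#' @export
writeLambdaStackTIFF <- function(stack, path, fullScale = fullScaleDefault) {
  d <- intensities(stack) / fullScale
  if (any(d > 1)) {
    warning("intensities above fullScale clipped on write")
    d <- pmin(d, 1)
  }
  pages <- lapply(seq_len(dim(d)[3]), function(b) d[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname writeLambdaStackTIFF
#' @param wavelengthsNm band wavelengths to attach on read
#' @param pixelSizeUm pixel size to attach on read
#' @export
readLambdaStackTIFF <- function(path, wavelengthsNm = seq(500, 580, by = 10),
                                pixelSizeUm = 0.16,
                                fullScale = fullScaleDefault) {
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (b in seq_along(pages)) {
    p <- pages[[b]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    d[, , b] <- p
  }
  LambdaStack(d * fullScale, wavelengthsNm, pixelSizeUm)
}

#' Write / read a time lapse as multi-page TIFF
#'
#' Pages are frames in temporal order.
#'
#' @param movie a \linkS4class{TimeLapse}
#' @param path output path
#' @param fullScale intensity corresponding to 1.0 in the file
#' @return \code{writeTimeLapseTIFF}: the path, invisibly;
#'   \code{readTimeLapseTIFF}: a \linkS4class{TimeLapse}
#' @export
writeTimeLapseTIFF <- function(movie, path, fullScale = fullScaleDefault) {
  d <- intensities(movie) / fullScale
  if (any(d > 1)) {
    warning("intensities above fullScale clipped on write")
    d <- pmin(d, 1)
  }
  pages <- lapply(seq_len(dim(d)[3]), function(t) d[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname writeTimeLapseTIFF
#' @param frameRateHz frame rate to attach on read
#' @param pixelSizeUm pixel size to attach on read
#' @export
readTimeLapseTIFF <- function(path, frameRateHz = 3.1, pixelSizeUm = 0.16,
                              fullScale = fullScaleDefault) {
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) {
    p <- pages[[t]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    d[, , t] <- p
  }
  TimeLapse(d * fullScale, frameRateHz, pixelSizeUm)
}

#' Write a PunctaSet as CSV
#'
#' One row per punctum: id, centroid (um and px), area, integrated
#' intensity, bounding box.
#'
#' @param ps a \linkS4class{PunctaSet}
#' @param path output path
#' @return the path, invisibly
#' @export
writePunctaCSV <- function(ps, path) {
  utils::write.csv(punctaTable(ps), path, row.names = FALSE)
  invisible(path)
}

#' Write a list of classified tracks as CSV
#'
#' One row per track: id, class, direction, mean velocity, number of runs,
#' total run length, flags.
#'
#' @param tracks list of \linkS4class{Track}
#' @param path output path
#' @return the path, invisibly
#' @export
writeTracksCSV <- function(tracks, path) {
  rows <- lapply(seq_along(tracks), function(i) {
    t <- tracks[[i]]
    data.frame(id = i, nPoints = length(t@frames),
               startFrame = if (length(t@frames)) min(t@frames) else NA,
               endFrame = if (length(t@frames)) max(t@frames) else NA,
               class = t@classification, direction = t@direction,
               meanVelocityUmPerS = t@meanVelocityUmPerS,
               nRuns = nrow(t@runs),
               totalRunLengthUm = sum(t@runs$runLengthUm),
               flags = paste(t@flags, collapse = ";"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a spectral profile as CSV (wavelength, weight)
#'
#' @param profile a \linkS4class{SpectralProfile}
#' @param path output path
#' @return the path, invisibly
#' @export
writeProfileCSV <- function(profile, path) {
  utils::write.csv(data.frame(wavelengthNm = wavelengths(profile),
                              weight = profileWeights(profile)),
                   path, row.names = FALSE)
  invisible(path)
}
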