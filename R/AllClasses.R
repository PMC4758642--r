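#' @import methods
NULL

#' FluorImage: a single-channel fluorescence image
#'
#' A 2D intensity grid together with its physical pixel size and an optional
#' channel label. Intensities are arbitrary camera units, finite and
#' non-negative; the pixel size converts pixel coordinates to microns.
#' Coordinates are 0-based with x increasing rightward (along the nerve cord,
#' anterior at the left) and y increasing downward; the centre of pixel
#' column j (1-based storage index) lies at x = (j - 0.5) * pixelSize(um).
#'
#' @slot data numeric matrix of intensities (rows = y, columns = x)
#' @slot pixelSizeUm positive scalar, microns per pixel
#' @slot channel character label, e.g. "GFP"
#' @export
setClass("FluorImage",
  representation(data = "matrix", pixelSizeUm = "numeric", channel = "character"),
  prototype(pixelSizeUm = 0.16, channel = ""))

setValidity("FluorImage", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("'data' must be a numeric matrix")
  if (any(!is.finite(d))) return("intensities must be finite")
  if (any(d < 0)) return("intensities must be non-negative")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    return("'pixelSizeUm' must be a positive scalar")
  TRUE
})

#' Construct a FluorImage
#'
#' @param data numeric matrix of non-negative intensities
#' @param pixelSizeUm microns per pixel (default 0.16, a typical 100X/EMCCD
#'   geometry where 512 px span about 80 um)
#' @param channel optional channel label
#' @return a \linkS4class{FluorImage}
#' @examples
#' img <- FluorImage(matrix(runif(100), 10, 10))
#' pixelSize(img)
#' @export
FluorImage <- function(data, pixelSizeUm = 0.16, channel = "") {
  new("FluorImage", data = as.matrix(data), pixelSizeUm = pixelSizeUm,
      channel = channel)
}

#' LambdaStack: a 9-band emission wavelength scan
#'
#' Co-registered images acquired across emission bands (by default 500-580 nm
#' at 10 nm intervals), stored as a 3D array with the band index last.
#'
#' @slot data numeric array (y, x, band)
#' @slot wavelengthsNm strictly increasing band centre wavelengths
#' @slot pixelSizeUm microns per pixel
#' @export
setClass("LambdaStack",
  representation(data = "array", wavelengthsNm = "numeric",
                 pixelSizeUm = "numeric"),
  prototype(pixelSizeUm = 0.16))

setValidity("LambdaStack", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("'data' must be a 3D array (y, x, band)")
  if (dim(d)[3] != length(object@wavelengthsNm))
    return("number of bands must match length(wavelengthsNm)")
  if (is.unsorted(object@wavelengthsNm, strictly = TRUE))
    return("wavelengths must be strictly increasing")
  if (any(!is.finite(d))) return("intensities must be finite")
  if (object@pixelSizeUm <= 0) return("'pixelSizeUm' must be positive")
  TRUE
})

#' Construct a LambdaStack
#'
#' @param data 3D numeric array (y, x, band)
#' @param wavelengthsNm band centre wavelengths; default 500-580 nm in 10 nm
#'   steps (9 bands)
#' @param pixelSizeUm microns per pixel
#' @return a \linkS4class{LambdaStack}
#' @export
LambdaStack <- function(data, wavelengthsNm = seq(500, 580, by = 10),
                        pixelSizeUm = 0.16) {
  new("LambdaStack", data = data, wavelengthsNm = wavelengthsNm,
      pixelSizeUm = pixelSizeUm)
}

#' SpectralProfile: a normalized emission spectrum
#'
#' Band weights of an emission spectrum sampled at the lambda-scan bands,
#' non-negative and summing to 1 (within 1e-9).
#'
#' @slot weights numeric band weights summing to 1
#' @slot wavelengthsNm band centre wavelengths
#' @slot label provenance label, e.g. "N2 autofluorescence reference"
#' @export
setClass("SpectralProfile",
  representation(weights = "numeric", wavelengthsNm = "numeric",
                 label = "character"),
  prototype(label = ""))

setValidity("SpectralProfile", function(object) {
  w <- object@weights
  if (length(w) != length(object@wavelengthsNm))
    return("weights and wavelengths must have equal length")
  if (any(!is.finite(w)) || any(w < 0)) return("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) return("weights must sum to 1 (within 1e-9)")
  if (is.unsorted(object@wavelengthsNm, strictly = TRUE))
    return("wavelengths must be strictly increasing")
  TRUE
})

#' Construct a SpectralProfile
#'
#' Weights are normalized to unit sum; all-zero weights are rejected.
#'
#' @param weights non-negative band weights (any scale; normalized internally)
#' @param wavelengthsNm band centre wavelengths (default 9 bands, 500-580 nm)
#' @param label provenance label
#' @return a \linkS4class{SpectralProfile}
#' @export
SpectralProfile <- function(weights, wavelengthsNm = seq(500, 580, by = 10),
                            label = "") {
  s <- sum(weights)
  if (!is.finite(s) || s <= 0) stop("profile weights must have a positive sum")
  new("SpectralProfile", weights = weights / s,
      wavelengthsNm = wavelengthsNm, label = label)
}

#' TimeLapse: an ordered stack of frames at constant frame rate
#'
#' @slot data numeric array (y, x, frame)
#' @slot frameRateHz frames per second (the acquisitions emulated here ran at
#'   3.1 frames/s)
#' @slot pixelSizeUm microns per pixel
#' @export
setClass("TimeLapse",
  representation(data = "array", frameRateHz = "numeric",
                 pixelSizeUm = "numeric"),
  prototype(frameRateHz = 3.1, pixelSizeUm = 0.16))

setValidity("TimeLapse", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("'data' must be a 3D array (y, x, frame)")
  if (dim(d)[3] < 2L) return("a time lapse needs at least 2 frames")
  if (object@frameRateHz <= 0) return("'frameRateHz' must be positive")
  if (object@pixelSizeUm <= 0) return("'pixelSizeUm' must be positive")
  TRUE
})

#' Construct a TimeLapse
#' @param data 3D numeric array (y, x, frame)
#' @param frameRateHz frames per second (default 3.1)
#' @param pixelSizeUm microns per pixel (default 0.16)
#' @return a \linkS4class{TimeLapse}
#' @export
TimeLapse <- function(data, frameRateHz = 3.1, pixelSizeUm = 0.16) {
  new("TimeLapse", data = data, frameRateHz = frameRateHz,
      pixelSizeUm = pixelSizeUm)
}

#' Kymograph: position-time intensity map along a line ROI
#'
#' Rows are frames (time increasing downward), columns are positions along
#' the line ROI. The orientation flag records that the anterior of the animal
#' (the retrograde direction) is at the left.
#'
#' @slot data numeric matrix (rows = frames, cols = positions)
#' @slot pixelSizeUm microns per pixel along the ROI
#' @slot frameIntervalS seconds between rows
#' @slot anteriorLeft logical; TRUE when decreasing x = anterior = retrograde
#' @export
setClass("Kymograph",
  representation(data = "matrix", pixelSizeUm = "numeric",
                 frameIntervalS = "numeric", anteriorLeft = "logical"),
  prototype(anteriorLeft = TRUE))

setValidity("Kymograph", function(object) {
  if (object@pixelSizeUm <= 0) return("'pixelSizeUm' must be positive")
  if (object@frameIntervalS <= 0) return("'frameIntervalS' must be positive")
  TRUE
})

#' PunctaSet: detected fluorescent objects
#'
#' One row per punctum with intensity-weighted centroid (um and px), pixel
#' area, area in um^2, integrated intensity (sum of member-pixel intensities)
#' and bounding box; plus the threshold used for detection and, when known,
#' the length of nerve cord analyzed.
#'
#' @slot puncta data.frame with columns id, xUm, yUm, xPx, yPx, areaPx,
#'   areaUm2, integratedIntensity, xminPx, xmaxPx, yminPx, ymaxPx
#' @slot threshold intensity threshold used for detection
#' @slot pixelSizeUm microns per pixel of the source image
#' @slot cordLengthUm length of cord analyzed (NA when not applicable)
#' @export
setClass("PunctaSet",
  representation(puncta = "data.frame", threshold = "numeric",
                 pixelSizeUm = "numeric", cordLengthUm = "numeric"),
  prototype(threshold = NA_real_, cordLengthUm = NA_real_))

setValidity("PunctaSet", function(object) {
  need <- c("id", "xUm", "yUm", "areaPx", "integratedIntensity")
  if (!all(need %in% names(object@puncta)))
    return(paste("puncta table must contain columns:", paste(need, collapse = ", ")))
  if (nrow(object@puncta) && any(object@puncta$integratedIntensity < 0))
    return("integrated intensities must be non-negative")
  TRUE
})

#' Track: one linked particle trajectory on a kymograph
#'
#' Positions are kymograph column indices (pixels along the cord) at strictly
#' increasing frame indices. Classification follows the transport criteria:
#' mobile when displacement accumulated over successive same-direction frames
#' reaches the mobility threshold, stationary when immobile for more than the
#' stationary spell length, otherwise excluded. Direction comes from the sign
#' of net displacement (decreasing x = anterior = retrograde).
#'
#' @slot frames integer frame indices (strictly increasing)
#' @slot xPx particle positions (pixels along the ROI)
#' @slot class one of "mobile", "stationary", "excluded", "unclassified"
#' @slot direction one of "anterograde", "retrograde", "none"
#' @slot meanVelocityUmPerS mean run velocity (NA unless mobile with runs)
#' @slot runs data.frame of movement events (see \code{\link{segmentRuns}})
#' @slot pixelSizeUm microns per pixel
#' @slot frameRateHz frames per second
#' @slot flags character vector of quality flags (e.g. "ambiguous-link")
#' @export
setClass("Track",
  representation(frames = "integer", xPx = "numeric", classification = "character",
                 direction = "character", meanVelocityUmPerS = "numeric",
                 runs = "data.frame", pixelSizeUm = "numeric",
                 frameRateHz = "numeric", flags = "character"),
  prototype(classification = "unclassified", direction = "none",
            meanVelocityUmPerS = NA_real_, runs = data.frame(),
            pixelSizeUm = 0.16, frameRateHz = 3.1, flags = character(0)))

setValidity("Track", function(object) {
  if (length(object@frames) != length(object@xPx))
    return("'frames' and 'xPx' must have equal length")
  if (length(object@frames) > 1L && any(diff(object@frames) <= 0))
    return("frame indices must be strictly increasing")
  if (!object@classification %in% c("mobile", "stationary", "excluded", "unclassified"))
    return("invalid track class")
  if (!object@direction %in% c("anterograde", "retrograde", "none"))
    return("invalid track direction")
  TRUE
})

#' Construct a Track
#' @param frames integer frame indices
#' @param xPx positions in pixels along the ROI
#' @param pixelSizeUm microns per pixel
#' @param frameRateHz frames per second
#' @param flags optional quality flags
#' @return an unclassified \linkS4class{Track}; see \code{\link{classifyTrack}}
#' @export
Track <- function(frames, xPx, pixelSizeUm = 0.16, frameRateHz = 3.1,
                  flags = character(0)) {
  new("Track", frames = as.integer(frames), xPx = as.numeric(xPx),
      pixelSizeUm = pixelSizeUm, frameRateHz = frameRateHz, flags = flags)
}

#' AlignmentResult: a pairwise global protein alignment
#'
#' Aligned strings (with "-" gap characters) of equal length, the alignment
#' score, and the identifiers of the two sequences. Ungapping either aligned
#' string recovers the corresponding input sequence.
#'
#' @slot idA,idB sequence identifiers
#' @slot alignedA,alignedB aligned strings with gaps
#' @slot score alignment score
#' @export
setClass("AlignmentResult",
  representation(idA = "character", idB = "character",
                 alignedA = "character", alignedB = "character",
                 score = "numeric"))

setValidity("AlignmentResult", function(object) {
  if (nchar(object@alignedA) != nchar(object@alignedB))
    return("aligned strings must have equal length")
  TRUE
})
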