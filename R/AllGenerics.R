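#' Accessors for cordQuant classes
#'
#' \code{intensities} returns the raw numeric data (matrix or array);
#' \code{pixelSize} the pixel size in microns; \code{channelLabel} the channel
#' label of a \linkS4class{FluorImage}; \code{wavelengths} the band centres of
#' a \linkS4class{LambdaStack} or \linkS4class{SpectralProfile};
#' \code{profileWeights} the normalized weights of a
#' \linkS4class{SpectralProfile}; \code{frameRate} the frame rate of a
#' \linkS4class{TimeLapse}; \code{punctaTable} the per-punctum data.frame and
#' \code{punctaCount} the number of detected puncta of a
#' \linkS4class{PunctaSet}; \code{trackClass} and \code{trackDirection} the
#' classification of a \linkS4class{Track}.
#'
#' @param x an object of the appropriate class
#' @return the accessed component
#' @name accessors
#' @aliases intensities pixelSize channelLabel wavelengths profileWeights
#'   frameRate punctaTable punctaCount trackClass trackDirection
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("channelLabel", function(x) standardGeneric("channelLabel"))
#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("profileWeights", function(x) standardGeneric("profileWeights"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("punctaTable", function(x) standardGeneric("punctaTable"))
#' @rdname accessors
#' @export
setGeneric("punctaCount", function(x) standardGeneric("punctaCount"))
#' @rdname accessors
#' @export
setGeneric("trackClass", function(x) standardGeneric("trackClass"))
#' @rdname accessors
#' @export
setGeneric("trackDirection", function(x) standardGeneric("trackDirection"))

#' @rdname accessors
setMethod("intensities", "FluorImage", function(x) x@data)
#' @rdname accessors
setMethod("intensities", "LambdaStack", function(x) x@data)
#' @rdname accessors
setMethod("intensities", "TimeLapse", function(x) x@data)
#' @rdname accessors
setMethod("intensities", "Kymograph", function(x) x@data)

#' @rdname accessors
setMethod("pixelSize", "FluorImage", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSize", "LambdaStack", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSize", "TimeLapse", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSize", "Kymograph", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSize", "PunctaSet", function(x) x@pixelSizeUm)

#' @rdname accessors
setMethod("channelLabel", "FluorImage", function(x) x@channel)
#' @rdname accessors
setMethod("wavelengths", "LambdaStack", function(x) x@wavelengthsNm)
#' @rdname accessors
setMethod("wavelengths", "SpectralProfile", function(x) x@wavelengthsNm)
#' @rdname accessors
setMethod("profileWeights", "SpectralProfile", function(x) x@weights)
#' @rdname accessors
setMethod("frameRate", "TimeLapse", function(x) x@frameRateHz)
#' @rdname accessors
setMethod("punctaTable", "PunctaSet", function(x) x@puncta)
#' @rdname accessors
setMethod("punctaCount", "PunctaSet", function(x) nrow(x@puncta))
#' @rdname accessors
setMethod("trackClass", "Track", function(x) x@classification)
#' @rdname accessors
setMethod("trackDirection", "Track", function(x) x@direction)

#' @describeIn accessors image dimensions (rows, cols)
#' @export
setMethod("dim", "FluorImage", function(x) dim(x@data))

setMethod("show", "FluorImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("FluorImage %dx%d px (%.3g um/px)%s  range [%.4g, %.4g]\n",
              d[1], d[2], object@pixelSizeUm,
              if (nzchar(object@channel)) paste0(" channel=", object@channel) else "",
              min(object@data), max(object@data)))
})

setMethod("show", "LambdaStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("LambdaStack %dx%d px, %d bands (%g-%g nm), %.3g um/px\n",
              d[1], d[2], d[3], min(object@wavelengthsNm),
              max(object@wavelengthsNm), object@pixelSizeUm))
})

setMethod("show", "SpectralProfile", function(object) {
  cat(sprintf("SpectralProfile [%s] %d bands %g-%g nm\n",
              object@label, length(object@weights),
              min(object@wavelengthsNm), max(object@wavelengthsNm)))
  print(round(stats::setNames(object@weights, object@wavelengthsNm), 4))
})

setMethod("show", "TimeLapse", function(object) {
  d <- dim(object@data)
  cat(sprintf("TimeLapse %dx%d px, %d frames @ %.3g fps, %.3g um/px\n",
              d[1], d[2], d[3], object@frameRateHz, object@pixelSizeUm))
})

setMethod("show", "Kymograph", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "Kymograph %d frames x %d positions, %.3g s/frame, %.3g um/px (anterior %s)\n",
    d[1], d[2], object@frameIntervalS, object@pixelSizeUm,
    if (object@anteriorLeft) "left" else "right"))
})

setMethod("show", "PunctaSet", function(object) {
  cat(sprintf("PunctaSet: %d puncta (threshold %.4g%s)\n",
              nrow(object@puncta), object@threshold,
              if (is.finite(object@cordLengthUm))
                sprintf(", cord %g um", object@cordLengthUm) else ""))
  if (nrow(object@puncta)) print(utils::head(object@puncta, 5))
})

setMethod("show", "Track", function(object) {
  n <- length(object@frames)
  cat(sprintf("Track: %d points, class=%s, direction=%s%s%s\n",
              n, object@classification, object@direction,
              if (is.finite(object@meanVelocityUmPerS))
                sprintf(", v=%.3g um/s", object@meanVelocityUmPerS) else "",
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ","), "]") else ""))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult %s vs %s: %d columns, score %.4g\n",
              object@idA, object@idB, nchar(object@alignedA), object@score))
})

#' Coerce a PunctaSet to a data.frame
#' @param x a PunctaSet
#' @param ... ignored
#' @export
as.data.frame.PunctaSet <- function(x, ...) x@puncta
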