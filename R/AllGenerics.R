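#' Airy radius in pixels
#'
#' Rayleigh radius of the Airy disc, `0.61 * wavelength / NA`, converted to
#' pixels.
#'
#' @param object an [AiryDisc-class].
#' @return positive numeric scalar, pixels.
#' @examples
#' radiusPx(airyDisc(670, 1.45, 140))
#' @export
setGeneric("radiusPx", function(object) standardGeneric("radiusPx"))

#' @rdname radiusPx
#' @export
setMethod("radiusPx", "AiryDisc", function(object) {
  0.61 * object@emissionWavelengthNm / object@numericalAperture /
    object@pixelSizeNm
})

#' Extract the boolean raster from a mask-like object
#'
#' @param object a [BinaryMask-class] or [CellFootprint-class].
#' @return logical matrix indexed `[y, x]`.
#' @export
setGeneric("maskRaster", function(object) standardGeneric("maskRaster"))

#' @rdname maskRaster
#' @export
setMethod("maskRaster", "BinaryMask", function(object) object@raster)

#' @rdname maskRaster
#' @export
setMethod("maskRaster", "CellFootprint", function(object) object@raster)

#' Threshold recorded in a binary mask
#'
#' @param object a [BinaryMask-class].
#' @return numeric scalar, the intensity threshold that produced the mask.
#' @export
setGeneric("thresholdValue", function(object) standardGeneric("thresholdValue"))

#' @rdname thresholdValue
#' @export
setMethod("thresholdValue", "BinaryMask", function(object) object@thresholdValue)

#' Number of timepoints / channels in a stack
#'
#' @param object an [ImageStack-class].
#' @return integer scalar.
#' @export
setGeneric("nTimepoints", function(object) standardGeneric("nTimepoints"))

#' @rdname nTimepoints
#' @export
setMethod("nTimepoints", "ImageStack", function(object) length(object@times))

#' @rdname nTimepoints
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname nTimepoints
#' @export
setMethod("nChannels", "ImageStack", function(object) length(object@channels))

#' Extract one frame from an image stack
#'
#' @param object an [ImageStack-class].
#' @param time timepoint index (1-based).
#' @param channel channel index (1-based) or channel role name.
#' @return numeric matrix.
#' @export
setGeneric("getFrame", function(object, time, channel) standardGeneric("getFrame"))

#' @rdname getFrame
#' @export
setMethod("getFrame", "ImageStack", function(object, time, channel) {
  if (is.character(channel)) {
    idx <- match(channel, object@channels)
    if (is.na(idx))
      stop(sprintf("channel '%s' not found; stack has: %s", channel,
                   paste(object@channels, collapse = ", ")))
    channel <- idx
  }
  nC <- length(object@channels)
  if (time < 1L || time > length(object@times))
    stop("timepoint index out of range")
  if (channel < 1L || channel > nC)
    stop("channel index out of range")
  object@frames[[(time - 1L) * nC + channel]]
})

#' Normalized values of a cell trace
#'
#' @param object a [CellTrace-class].
#' @return numeric vector (F/F_pre normalized intensities).
#' @export
setGeneric("normalizedValues", function(object) standardGeneric("normalizedValues"))

#' @rdname normalizedValues
#' @export
setMethod("normalizedValues", "CellTrace", function(object) object@normalized)

#' Trace time axis in seconds
#'
#' @param object a [CellTrace-class].
#' @return numeric vector of frame times (negative = pre-treatment).
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))

#' @rdname traceTimes
#' @export
setMethod("traceTimes", "CellTrace", function(object) object@timesS)

setMethod("show", "AiryDisc", function(object) {
  cat(sprintf("AiryDisc: %.0f nm emission, NA %.2f, %.0f nm pixels -> radius %.3f px\n",
              object@emissionWavelengthNm, object@numericalAperture,
              object@pixelSizeNm, radiusPx(object)))
})

setMethod("show", "ScaleProfile", function(object) {
  cat(sprintf("ScaleProfile (%s): scales x{%s} Airy radius, threshold %.2f SD, dilation %d px, %s\n",
              object@organelleClass,
              paste(object@scaleMultiples, collapse = ","),
              object@thresholdSdFactor, object@dilationPx,
              object@productNormalization))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@raster)
  cat(sprintf("BinaryMask %dx%d: %d positive px (%.1f%%), threshold %.4g\n",
              d[1], d[2], sum(object@raster),
              100 * mean(object@raster), object@thresholdValue))
})

setMethod("show", "CellFootprint", function(object) {
  d <- dim(object@raster)
  cat(sprintf("CellFootprint %dx%d (%s): %d px (%.1f%%)\n",
              d[1], d[2], object@method, sum(object@raster),
              100 * mean(object@raster)))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("ImageStack: %d timepoint(s) x %d channel(s) [%s], %dx%d px, %.0f nm/px\n",
              length(object@times), length(object@channels),
              paste(object@channels, collapse = ", "), d[1], d[2],
              object@pixelSizeNm))
})

setMethod("show", "CellTrace", function(object) {
  cat(sprintf("CellTrace %s (experiment %s): %d frames, %d pre-treatment, background %.3g\n",
              object@cellId, object@experimentId, length(object@timesS),
              length(object@preWindow), object@background))
})

setMethod("show", "TurnoverModel", function(object) {
  cat("First-order turnover model\n")
  cat(sprintf("  copies:     %.4g molecules/cell\n", object@copies))
  cat(sprintf("  turnover:   %.4g cycles/s per molecule\n", object@turnoverPerS))
  cat(sprintf("  flux:       %.4g molecules/s\n", object@flux))
  cat(sprintf("  pool:       %.4g molecules/cell\n", object@pool))
  cat(sprintf("  k (%s): %.4g 1/s\n", object@kSource, object@k))
  cat(sprintf("  half-life:  %.4g s (%.1f min)\n", object@tHalfS,
              object@tHalfS / 60))
})

setMethod("show", "DecayFit", function(object) {
  cat(sprintf("DecayFit: k = %.6g 1/s (t1/2 = %.4g s), f0 = %.4g, plateau = %.4g%s, RMS %.3g on %d points\n",
              object@kFit, if (object@kFit > 0) log(2) / object@kFit else Inf,
              object@f0, object@plateau,
              if (object@plateauFixed) " (fixed)" else "",
              object@residualRms, object@nPoints))
})

setMethod("show", "SceneSpec", function(object) {
  geom <- if (object@organelleClass == "mitochondria")
    sprintf("%d capsules", object@nStructures)
  else sprintf("tubule density %.2f", object@tubuleDensity)
  cat(sprintf("SceneSpec: %dx%d px (%s), %s, enrichment x%.2f, PSF sigma %.2f px, seed %d\n",
              object@widthPx, object@heightPx, object@organelleClass, geom,
              object@enrichmentFactor, object@psfSigmaPx, object@seed))
})
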