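# TIFF and sidecar I/O.  Intensities are stored as 16-bit unsigned pages
# (values rounded and clipped to 0..65535), so integer photon counts
# round-trip exactly.

TIFF_MAX <- 65535

#' Write an image stack to a multi-page TIFF
#'
#' Pages are written time-major then channel-major (frame 1 channel 1,
#' frame 1 channel 2, frame 2 channel 1, ...), as 16-bit unsigned samples.
#' Values are rounded and clipped to 0..65535 (with a warning if clipping
#' occurs).  A JSON sidecar (`<path>.json`) records the channel roles,
#' times and pixel size so that [readStack()] can restore the stack without
#' external metadata.
#'
#' @param stack an [ImageStack-class].
#' @param path output TIFF path.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @seealso [readStack()]
#' @export
writeStack <- function(stack, path, sidecar = TRUE) {
  stopifnot(is(stack, "ImageStack"))
  pages <- lapply(stack@frames, function(f) {
    v <- round(f)
    if (any(v < 0) || any(v > TIFF_MAX)) {
      warning("intensities clipped to 0..65535 for 16-bit TIFF output")
      v <- pmin(pmax(v, 0), TIFF_MAX)
    }
    v / TIFF_MAX
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (sidecar) {
    meta <- list(channels = stack@channels, times_s = stack@times,
                 pixel_size_nm = stack@pixelSizeNm,
                 n_timepoints = nTimepoints(stack),
                 n_channels = nChannels(stack))
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' Pages are interpreted time-major then channel-major.  Channel roles,
#' times and pixel size come from the JSON sidecar written by
#' [writeStack()], or can be supplied (arguments override the sidecar).
#' The declared channels-by-timepoints layout must match the page count
#' exactly.
#'
#' @param path TIFF path.
#' @param channels character vector of channel roles; overrides sidecar.
#' @param times numeric vector of frame times (s); overrides sidecar.
#' @param pixelSizeNm pixel size (nm); overrides sidecar.
#' @return an [ImageStack-class] with integer intensities restored.
#' @export
readStack <- function(path, channels = NULL, times = NULL, pixelSizeNm = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  sidecarPath <- paste0(path, ".json")
  if (file.exists(sidecarPath))
    meta <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  if (is.null(channels)) channels <- meta$channels
  if (is.null(times)) times <- meta$times_s
  if (is.null(pixelSizeNm)) pixelSizeNm <- meta$pixel_size_nm %||% 140
  if (is.null(channels)) channels <- "channel1"
  nC <- length(channels)
  if (length(pages) %% nC != 0L)
    stop(sprintf("found %d pages, not a multiple of %d declared channels",
                 length(pages), nC))
  nT <- length(pages) %/% nC
  if (is.null(times)) times <- seq_len(nT) - 1
  if (length(times) != nT)
    stop(sprintf("declared %d timepoints x %d channels but file has %d pages",
                 length(times), nC, length(pages)))
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra samples if present
    round(p * TIFF_MAX)
  })
  imageStack(frames, channels, times, pixelSizeNm)
}

#' Write a binary mask as an 8-bit TIFF with JSON metadata
#'
#' The mask is written as 0/255 pixels; a JSON sidecar records the
#' threshold, the masking recipe and a run-length encoding of the raster
#' (column-major), enabling exact round-trips without reading the TIFF.
#'
#' @param mask a [BinaryMask-class].
#' @param path output TIFF path.
#' @param airy optional [AiryDisc-class] recorded in the metadata.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path, airy = NULL) {
  stopifnot(is(mask, "BinaryMask"))
  tiff::writeTIFF(mask@raster * 1.0, path, bits.per.sample = 8L)
  r <- rle(as.vector(mask@raster))
  meta <- list(
    source_frame_id = mask@sourceFrameId,
    threshold_value = mask@thresholdValue,
    shape = dim(mask@raster),
    positive_px = sum(mask@raster),
    rle = list(lengths = r$lengths, values = r$values)
  )
  if (!is.null(mask@profile)) {
    p <- mask@profile
    meta$profile <- list(organelle_class = p@organelleClass,
                         scale_multiples = p@scaleMultiples,
                         threshold_sd_factor = p@thresholdSdFactor,
                         dilation_px = p@dilationPx,
                         product_normalization = p@productNormalization)
  }
  if (!is.null(airy))
    meta$airy <- list(emission_wavelength_nm = airy@emissionWavelengthNm,
                      numerical_aperture = airy@numericalAperture,
                      pixel_size_nm = airy@pixelSizeNm,
                      radius_px = radiusPx(airy))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a synthetic scene to TIFF with a ground-truth sidecar
#'
#' The marker and sensor channels go into one two-page TIFF; the sidecar
#' JSON holds the scene parameters and the organelle mask as a run-length
#' encoding.
#'
#' @param scene list from [generateOrganelleScene()].
#' @param spec the [SceneSpec-class] that produced it.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeScene <- function(scene, spec, path) {
  stk <- imageStack(list(scene$marker, scene$sensor),
                    channels = c("marker", "sensor"), times = 0,
                    pixelSizeNm = spec@pixelSizeNm)
  writeStack(stk, path, sidecar = FALSE)
  r <- rle(as.vector(scene$truth@organelleMask))
  meta <- list(
    channels = c("marker", "sensor"), times_s = 0,
    pixel_size_nm = spec@pixelSizeNm,
    spec = list(width_px = spec@widthPx, height_px = spec@heightPx,
                pixel_size_nm = spec@pixelSizeNm,
                organelle_class = spec@organelleClass,
                n_structures = spec@nStructures,
                tubule_density = spec@tubuleDensity,
                structure_width_px = spec@structureWidthPx,
                length_range_px = spec@lengthRangePx,
                marker_amplitude = spec@markerAmplitude,
                sensor_background = spec@sensorBackground,
                enrichment_factor = spec@enrichmentFactor,
                psf_sigma_px = spec@psfSigmaPx,
                read_noise_sd = spec@readNoiseSd,
                camera_offset = spec@cameraOffset, seed = spec@seed),
    mask_rle = list(lengths = r$lengths, values = r$values),
    mask_shape = dim(scene$truth@organelleMask)
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
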