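#' Segment the cell footprint
#'
#' Either an automatic Otsu segmentation (Gaussian smoothing at one Airy
#' radius, Otsu threshold, keep the largest connected component, fill
#' holes) or rasterization of a user-supplied ROI mask.  The footprint is
#' the region within which all enrichment statistics are computed.
#'
#' @param image numeric matrix (any channel with cell-wide signal).
#' @param method `"otsu"` or `"user_roi"`.
#' @param roi logical matrix for `method = "user_roi"`.
#' @param airy an [AiryDisc-class] setting the smoothing scale.
#' @param sourceFrameId identifier recorded in the result.
#' @return a [CellFootprint-class].
#' @examples
#' img <- matrix(10, 64, 64)
#' img[20:44, 20:44] <- 100
#' fp <- cellFootprint(img, "otsu")
#' sum(maskRaster(fp))
#' @export
cellFootprint <- function(image, method = c("otsu", "user_roi"), roi = NULL,
                          airy = airyDisc(), sourceFrameId = "frame") {
  method <- match.arg(method)
  stopIfNotFinite(image)
  if (method == "user_roi") {
    if (is.null(roi)) stop("method 'user_roi' requires a logical `roi` matrix")
    if (!identical(dim(roi), dim(image)))
      stop("roi must have the same shape as the image")
    ras <- roi & TRUE
    if (!any(ras)) stop("supplied ROI is empty")
    return(new("CellFootprint", raster = ras, method = "user_roi",
               sourceFrameId = as.character(sourceFrameId)))
  }
  smoothed <- gaussianBlur(image, radiusPx(airy))
  rng <- range(smoothed)
  if (diff(rng) <= 1e-9 * max(abs(rng), 1))
    stop("image has no separable foreground (constant intensity); supply a user ROI")
  y <- (smoothed - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(y), range = c(0, 1))
  fg <- y > thr
  if (!any(fg))
    stop("Otsu segmentation found no foreground; supply a user ROI")
  lbl <- EBImage::bwlabel(EBImage::Image(fg))
  counts <- table(as.integer(lbl)[as.integer(lbl) > 0L])
  keep <- as.integer(names(counts)[which.max(counts)])
  comp <- EBImage::fillHull(EBImage::Image(lbl == keep))
  ras <- matrix(as.logical(comp > 0), nrow(image), ncol(image))
  new("CellFootprint", raster = ras, method = "otsu",
      sourceFrameId = as.character(sourceFrameId))
}

#' Normalize a sensor image to its mean over the cell
#'
#' Divides the sensor image by its mean over the cell footprint, so the
#' normalized image averages to 1 over the cell.  This is the "normalized
#' to the average cell intensity" convention used when comparing biosensor
#' intensity across cells.
#'
#' @param sensor numeric matrix.
#' @param footprint a [CellFootprint-class] (or logical matrix).
#' @return numeric matrix, `sensor / mean(sensor[footprint])`.
#' @export
normalizeToCellMean <- function(sensor, footprint) {
  fp <- if (is(footprint, "CellFootprint")) footprint@raster else footprint
  if (!any(fp)) stop("footprint is empty")
  m <- mean(sensor[fp])
  if (!is.finite(m) || m <= 0)
    stop("cell mean must be positive to normalize")
  sensor / m
}

#' Biosensor enrichment at an organelle mask
#'
#' Mean sensor intensity over the organelle mask (restricted to the cell
#' footprint) divided by the mean over the rest of the footprint.  The
#' ratio is invariant to any positive rescaling of the sensor channel.
#'
#' @param sensor numeric matrix.
#' @param organelleMask a [BinaryMask-class] (or logical matrix).
#' @param footprint a [CellFootprint-class] (or logical matrix); defaults
#'   to the whole frame.
#' @param frameIndex,timeS metadata carried into the result.
#' @return one-row data.frame with columns `frame_index`, `time_s`,
#'   `mean_inside`, `mean_outside`, `cell_mean`, `enrichment`.
#' @examples
#' scn <- generateOrganelleScene(sceneSpec(seed = 7, psfSigmaPx = 0,
#'                                         readNoiseSd = 0, cameraOffset = 0))
#' enrichmentRatio(scn$truth@expectedSensor, scn$truth@organelleMask)
#' @export
enrichmentRatio <- function(sensor, organelleMask, footprint = NULL,
                            frameIndex = 1L, timeS = NA_real_) {
  msk <- if (is(organelleMask, "BinaryMask")) organelleMask@raster else organelleMask
  fp <- if (is.null(footprint)) matrix(TRUE, nrow(sensor), ncol(sensor))
        else if (is(footprint, "CellFootprint")) footprint@raster
        else footprint
  inside <- msk & fp
  outside <- fp & !msk
  if (!any(inside))
    stop("organelle mask does not intersect the cell footprint (empty inside region)")
  if (!any(outside))
    stop("cell footprint is entirely covered by the mask (empty outside region)")
  mi <- mean(sensor[inside])
  mo <- mean(sensor[outside])
  if (mo <= 0) stop("mean outside the mask must be positive")
  data.frame(frame_index = as.integer(frameIndex), time_s = as.numeric(timeS),
             mean_inside = mi, mean_outside = mo,
             cell_mean = mean(sensor[fp]), enrichment = mi / mo)
}

#' Enrichment time course over a stack
#'
#' For every timepoint, regenerates the organelle mask from the marker
#' channel (organelles move between frames) and measures sensor enrichment
#' inside versus outside the mask within the cell footprint.  Optionally
#' normalizes the enrichment series to its mean over pre-treatment frames
#' (times < 0).
#'
#' @param stack an [ImageStack-class].
#' @param markerChannel,sensorChannel channel role names or indices.
#' @param profile a [ScaleProfile-class].
#' @param airy an [AiryDisc-class].
#' @param footprint a [CellFootprint-class] or logical matrix; `NULL`
#'   (default) treats the whole field as the cell.
#' @param perFrameMask regenerate the mask each frame (default TRUE); FALSE
#'   reuses the first frame's mask.
#' @param normalizeToPre if TRUE and pre-treatment frames exist, adds a
#'   `normalized_enrichment` column (enrichment / pre-treatment mean).
#' @return data.frame, one row per timepoint, as in [enrichmentRatio()]
#'   plus `normalized_enrichment` when applicable.
#' @export
enrichmentTimecourse <- function(stack, markerChannel = "marker",
                                 sensorChannel = "sensor",
                                 profile = scaleProfile("mitochondria"),
                                 airy = airyDisc(), footprint = NULL,
                                 perFrameMask = TRUE, normalizeToPre = TRUE) {
  stopifnot(is(stack, "ImageStack"))
  nT <- nTimepoints(stack)
  rows <- vector("list", nT)
  mask <- NULL
  for (t in seq_len(nT)) {
    marker <- getFrame(stack, t, markerChannel)
    sensor <- getFrame(stack, t, sensorChannel)
    if (perFrameMask || is.null(mask))
      mask <- makeOrganelleMask(marker, profile, airy,
                                sourceFrameId = sprintf("t%03d", t))
    rows[[t]] <- enrichmentRatio(sensor, mask, footprint,
                                 frameIndex = t, timeS = stack@times[t])
  }
  out <- do.call(rbind, rows)
  if (normalizeToPre && any(out$time_s < 0)) {
    pre <- mean(out$enrichment[out$time_s < 0])
    out$normalized_enrichment <- out$enrichment / pre
  }
  out
}
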