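#' Construct an Airy disc descriptor
#'
#' The Airy radius follows the Rayleigh criterion, `0.61 * wavelength / NA`,
#' converted to pixels via the pixel size.  Defaults correspond to far-red
#' emission through a high-NA oil objective, the channel typically used for
#' the organelle marker.
#'
#' @param emissionWavelengthNm emission wavelength, nm (default 670).
#' @param numericalAperture objective NA (default 1.45).
#' @param pixelSizeNm pixel size at the sample, nm (default 140).
#' @return an [AiryDisc-class].
#' @examples
#' a <- airyDisc()
#' radiusPx(a)
#' @export
airyDisc <- function(emissionWavelengthNm = 670,
                     numericalAperture = 1.45,
                     pixelSizeNm = 140) {
  new("AiryDisc",
      emissionWavelengthNm = as.numeric(emissionWavelengthNm),
      numericalAperture = as.numeric(numericalAperture),
      pixelSizeNm = as.numeric(pixelSizeNm))
}

#' Construct a wavelet masking recipe
#'
#' The defaults encode the standard recipes: the ER (a fine reticular
#' network) uses Gaussian scales at 1 and 2 Airy radii and no dilation;
#' mitochondria (thicker, brighter structures) use scales 1--4 and a
#' 2-pixel dilation so the mask covers the whole organelle footprint.  Both
#' threshold the wavelet product at 0.5 standard deviations of the original
#' image intensity.
#'
#' @param organelleClass `"ER"` or `"mitochondria"`.
#' @param scaleMultiples strictly increasing positive integers; defaults to
#'   `c(1, 2)` for ER and `1:4` for mitochondria.
#' @param thresholdSdFactor threshold in SDs of the original image
#'   (default 0.5).
#' @param dilationPx mask dilation radius in pixels; defaults to 0 (ER) or
#'   2 (mitochondria).
#' @param productNormalization `"geometric_mean"` (default) or
#'   `"raw_product"`; the geometric mean restores intensity units so the
#'   product is dimensionally comparable to the SD threshold.
#' @return a [ScaleProfile-class].
#' @examples
#' scaleProfile("mitochondria")
#' scaleProfile("ER")
#' @export
scaleProfile <- function(organelleClass = c("ER", "mitochondria"),
                         scaleMultiples = NULL,
                         thresholdSdFactor = 0.5,
                         dilationPx = NULL,
                         productNormalization = c("geometric_mean", "raw_product")) {
  organelleClass <- match.arg(organelleClass)
  productNormalization <- match.arg(productNormalization)
  if (is.null(scaleMultiples))
    scaleMultiples <- if (organelleClass == "ER") c(1L, 2L) else 1:4
  if (is.null(dilationPx))
    dilationPx <- if (organelleClass == "ER") 0L else 2L
  new("ScaleProfile",
      organelleClass = organelleClass,
      scaleMultiples = as.integer(scaleMultiples),
      thresholdSdFactor = as.numeric(thresholdSdFactor),
      dilationPx = as.integer(dilationPx),
      productNormalization = productNormalization)
}

#' Gaussian-filtered image stack at multiple scales
#'
#' Filters the image with Gaussian kernels whose sigma (in pixels) is each
#' scale multiple times the Airy radius, using symmetric-reflection
#' boundary handling.  This is the first stage of the wavelet-product
#' segmentation.
#'
#' @param image numeric matrix `[y, x]`, finite-valued.
#' @param airy an [AiryDisc-class].
#' @param scaleMultiples positive multiples of the Airy radius (default
#'   taken from a profile via [makeOrganelleMask()]).
#' @return list of filtered matrices, one per scale, same shape as `image`.
#' @examples
#' img <- matrix(rpois(64, 10), 8, 8)
#' fs <- gaussianFilteredStack(img, airyDisc(), c(1, 2))
#' length(fs)
#' @export
gaussianFilteredStack <- function(image, airy, scaleMultiples) {
  stopifnot(is.matrix(image), is(airy, "AiryDisc"))
  stopIfNotFinite(image)
  if (any(scaleMultiples <= 0)) stop("scale multiples must be positive")
  r <- radiusPx(airy)
  lapply(scaleMultiples, function(m) gaussianBlur(image, m * r))
}

#' Wavelet images from a filtered stack
#'
#' Each filtered image has the image filtered at the next larger scale
#' subtracted from it: N scales give N - 1 band-pass (difference of
#' Gaussian) wavelet planes.  Values are kept unclamped.
#'
#' @param filteredStack list of >= 2 equally shaped matrices, ordered fine
#'   to coarse.
#' @return list of N - 1 wavelet matrices.
#' @examples
#' img <- matrix(rpois(64, 10), 8, 8)
#' ws <- waveletImages(gaussianFilteredStack(img, airyDisc(), 1:4))
#' length(ws)
#' @export
waveletImages <- function(filteredStack) {
  n <- length(filteredStack)
  if (n < 2L) stop("need at least 2 filtered scales to form wavelets")
  lapply(seq_len(n - 1L), function(i) filteredStack[[i]] - filteredStack[[i + 1L]])
}

#' Multiscale wavelet product
#'
#' Clamps each wavelet plane at zero (organelle structures are bright, so
#' only positive band-pass responses are meaningful) and multiplies the
#' planes elementwise.  Under `"geometric_mean"` normalization the product
#' is raised to the power 1/N so the result carries intensity units and can
#' be compared against an intensity threshold; `"raw_product"` returns the
#' plain clamped product (units intensity^N).
#'
#' @param wavelets list of >= 1 equally shaped wavelet matrices.
#' @param normalization `"geometric_mean"` (default) or `"raw_product"`.
#' @return numeric matrix, non-negative.
#' @examples
#' w <- list(matrix(1, 2, 2), matrix(4, 2, 2), matrix(16, 2, 2))
#' waveletProduct(w)[1, 1]  # cube root of 64 = 4
#' @export
waveletProduct <- function(wavelets,
                           normalization = c("geometric_mean", "raw_product")) {
  normalization <- match.arg(normalization)
  if (length(wavelets) < 1L) stop("need at least one wavelet")
  d <- dim(wavelets[[1]])
  prod <- matrix(1, d[1], d[2])
  for (w in wavelets) {
    if (!identical(dim(w), d)) stop("wavelet shape mismatch")
    prod <- prod * pmax(w, 0)
  }
  if (normalization == "geometric_mean") prod^(1 / length(wavelets)) else prod
}

#' Threshold a wavelet product against the original image SD
#'
#' The threshold is `factor` times the population standard deviation of the
#' original image (by default over the full frame); pixels with product
#' strictly above the threshold are masked.  A constant original image has
#' SD 0 and yields an empty mask rather than an error.
#'
#' @param product non-negative matrix from [waveletProduct()].
#' @param original the original (unfiltered) image, same shape.
#' @param factor positive SD multiplier (default 0.5).
#' @param roi optional logical matrix restricting the SD computation to an
#'   analysis region (e.g. the cell footprint).
#' @param profile optional [ScaleProfile-class] recorded in the result.
#' @param sourceFrameId identifier recorded in the result.
#' @return a [BinaryMask-class].
#' @export
thresholdMask <- function(product, original, factor = 0.5, roi = NULL,
                          profile = NULL, sourceFrameId = "frame") {
  if (!identical(dim(product), dim(original)))
    stop("product and original must have the same shape")
  if (length(factor) != 1L || factor <= 0) stop("factor must be positive")
  vals <- if (is.null(roi)) original else original[roi]
  thr <- factor * sdPop(as.numeric(vals))
  # SD 0 (constant image): nothing exceeds the threshold by definition --
  # any residual wavelet values are pure floating-point noise
  raster <- if (thr == 0) matrix(FALSE, nrow(product), ncol(product))
            else product > thr
  new("BinaryMask", raster = raster, profile = profile,
      thresholdValue = thr, sourceFrameId = as.character(sourceFrameId))
}

#' Dilate a binary mask with a Euclidean disk
#'
#' Binary dilation with the disk structuring element
#' \{(dy, dx) : dy^2 + dx^2 <= r^2\}; radius 0 is the identity.  Pixels
#' beyond the image border are dropped.
#'
#' @param mask a [BinaryMask-class] or logical matrix.
#' @param radiusPx non-negative integer radius.
#' @return same type as `mask`.
#' @examples
#' m <- matrix(FALSE, 7, 7); m[4, 4] <- TRUE
#' sum(dilateMask(m, 2))  # 13-pixel discrete disk
#' @export
dilateMask <- function(mask, radiusPx) {
  if (length(radiusPx) != 1L || radiusPx < 0 || radiusPx != floor(radiusPx))
    stop("dilation radius must be a non-negative integer")
  ras <- if (is(mask, "BinaryMask")) mask@raster else mask
  if (radiusPx > 0 && any(ras)) {
    off <- diskOffsets(radiusPx)
    ny <- nrow(ras); nx <- ncol(ras)
    out <- matrix(FALSE, ny, nx)
    for (i in seq_len(nrow(off))) {
      dy <- off$dy[i]; dx <- off$dx[i]
      ys <- max(1, 1 + dy):min(ny, ny + dy)
      xs <- max(1, 1 + dx):min(nx, nx + dx)
      out[ys, xs] <- out[ys, xs] | ras[ys - dy, xs - dx]
    }
    ras <- out
  }
  if (is(mask, "BinaryMask")) {
    mask@raster <- ras
    mask
  } else ras
}

#' Generate an organelle mask by the multiscale wavelet-product procedure
#'
#' Full segmentation pipeline for an organelle-marker image: Gaussian
#' filtering at the profile's multiples of the Airy radius, consecutive
#' differences to form wavelet planes, clamped elementwise product
#' (geometric-mean normalized by default), thresholding at
#' `thresholdSdFactor` standard deviations of the original image, and --
#' for profiles that request it -- a Euclidean-disk dilation.
#'
#' Under geometric-mean normalization the mask is invariant to affine
#' intensity transforms of the input (`a * image + b`, `a > 0`): the
#' wavelets scale by `a` and lose `b`, the geometric mean scales by `a`,
#' and so does the SD threshold.
#'
#' @param image numeric matrix, the marker channel.
#' @param profile a [ScaleProfile-class].
#' @param airy an [AiryDisc-class].
#' @param roi optional logical matrix restricting the threshold SD region.
#' @param sourceFrameId identifier recorded in the result.
#' @return a [BinaryMask-class] with the threshold and profile recorded.
#' @examples
#' scn <- generateOrganelleScene(sceneSpec(seed = 7))
#' msk <- makeOrganelleMask(scn$marker, scaleProfile("mitochondria"), airyDisc())
#' msk
#' @export
makeOrganelleMask <- function(image, profile, airy, roi = NULL,
                              sourceFrameId = "frame") {
  stopifnot(is(profile, "ScaleProfile"), is(airy, "AiryDisc"))
  filtered <- gaussianFilteredStack(image, airy, profile@scaleMultiples)
  wavelets <- waveletImages(filtered)
  prod <- waveletProduct(wavelets, profile@productNormalization)
  mask <- thresholdMask(prod, image, profile@thresholdSdFactor, roi = roi,
                        profile = profile, sourceFrameId = sourceFrameId)
  if (profile@dilationPx > 0L) mask <- dilateMask(mask, profile@dilationPx)
  mask
}
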