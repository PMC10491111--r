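#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Airy disc geometry of the imaging system
#'
#' Holds the emission wavelength, objective numerical aperture and camera
#' pixel size, from which the Rayleigh radius of the diffraction-limited
#' Airy disc is derived.  The Airy radius (in pixels) sets the length
#' scales of the wavelet decomposition used for organelle segmentation.
#'
#' @slot emissionWavelengthNm emission wavelength in nanometres.
#' @slot numericalAperture objective numerical aperture.
#' @slot pixelSizeNm camera pixel size in nanometres (at the sample).
#'
#' @seealso [airyDisc()], [radiusPx()]
#' @export
setClass("AiryDisc",
  representation(
    emissionWavelengthNm = "numeric",
    numericalAperture = "numeric",
    pixelSizeNm = "numeric"
  )
)

setValidity("AiryDisc", function(object) {
  msg <- character()
  for (s in c("emissionWavelengthNm", "numericalAperture", "pixelSizeNm")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive finite number", s))
  }
  if (length(msg)) msg else TRUE
})

#' Wavelet masking recipe for one organelle class
#'
#' Bundles the parameters of the multi-scale wavelet-product segmentation:
#' which multiples of the Airy radius to filter at, the threshold expressed
#' in standard deviations of the original image, the post-threshold dilation
#' radius, and how the wavelet product is normalized before thresholding.
#'
#' The default recipes are \code{scaleProfile("ER")} (scales 1,2; no
#' dilation) and \code{scaleProfile("mitochondria")} (scales 1..4; 2-pixel
#' dilation), both with a 0.5-SD threshold and geometric-mean product
#' normalization.
#'
#' @slot organelleClass `"ER"` or `"mitochondria"`.
#' @slot scaleMultiples strictly increasing positive integers (>= 2 of them);
#'   Gaussian filter sigmas are these multiples times the Airy radius.
#' @slot thresholdSdFactor positive multiplier of the original image SD.
#' @slot dilationPx non-negative integer dilation radius applied to the mask.
#' @slot productNormalization `"geometric_mean"` (N-th root of the clamped
#'   wavelet product, so the product carries intensity units) or
#'   `"raw_product"`.
#'
#' @seealso [scaleProfile()], [makeOrganelleMask()]
#' @export
setClass("ScaleProfile",
  representation(
    organelleClass = "character",
    scaleMultiples = "integer",
    thresholdSdFactor = "numeric",
    dilationPx = "integer",
    productNormalization = "character"
  )
)

setValidity("ScaleProfile", function(object) {
  msg <- character()
  if (!object@organelleClass %in% c("ER", "mitochondria"))
    msg <- c(msg, "organelleClass must be 'ER' or 'mitochondria'")
  sm <- object@scaleMultiples
  if (length(sm) < 2L || any(sm <= 0L) || any(diff(sm) <= 0L))
    msg <- c(msg, "scaleMultiples must be >= 2 strictly increasing positive integers")
  if (length(object@thresholdSdFactor) != 1L || object@thresholdSdFactor <= 0)
    msg <- c(msg, "thresholdSdFactor must be a single positive number")
  if (length(object@dilationPx) != 1L || object@dilationPx < 0L)
    msg <- c(msg, "dilationPx must be a single non-negative integer")
  if (!object@productNormalization %in% c("geometric_mean", "raw_product"))
    msg <- c(msg, "productNormalization must be 'geometric_mean' or 'raw_product'")
  if (length(msg)) msg else TRUE
})

setClassUnion("ScaleProfileOrNULL", c("ScaleProfile", "NULL"))

#' Binary organelle mask
#'
#' A per-frame boolean raster marking organelle footprint pixels, together
#' with the recipe and threshold that produced it.  Rasters are row-major
#' matrices indexed `[y, x]`.
#'
#' @slot raster logical matrix, same shape as the source image.
#' @slot profile the [ScaleProfile-class] used, or `NULL` for ad-hoc masks.
#' @slot thresholdValue the intensity threshold that was applied (>= 0).
#' @slot sourceFrameId identifier of the source frame.
#'
#' @seealso [makeOrganelleMask()], [maskRaster()]
#' @export
setClass("BinaryMask",
  representation(
    raster = "matrix",
    profile = "ScaleProfileOrNULL",
    thresholdValue = "numeric",
    sourceFrameId = "character"
  )
)

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (!is.logical(object@raster))
    msg <- c(msg, "raster must be a logical matrix")
  if (length(object@thresholdValue) != 1L ||
      is.na(object@thresholdValue) || object@thresholdValue < 0)
    msg <- c(msg, "thresholdValue must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Cell footprint mask
#'
#' Boolean raster of the pixels belonging to the cell (the region within
#' which enrichment ratios and mean intensities are computed), plus the
#' method used to obtain it.
#'
#' @slot raster logical matrix.
#' @slot method `"otsu"` or `"user_roi"`.
#' @slot sourceFrameId identifier of the source frame.
#'
#' @seealso [cellFootprint()]
#' @export
setClass("CellFootprint",
  representation(
    raster = "matrix",
    method = "character",
    sourceFrameId = "character"
  )
)

setValidity("CellFootprint", function(object) {
  msg <- character()
  if (!is.logical(object@raster))
    msg <- c(msg, "raster must be a logical matrix")
  if (!object@method %in% c("otsu", "user_roi"))
    msg <- c(msg, "method must be 'otsu' or 'user_roi'")
  if (!any(object@raster))
    msg <- c(msg, "footprint must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic organelle scene
#'
#' Describes one two-channel synthetic field of view: organelle geometry
#' (mitochondria as capsules, or an ER-like reticular network), a marker
#' channel lit on the organelle footprint, a sensor channel with a
#' configurable enrichment factor over organelle pixels, and the imaging
#' model (Gaussian PSF, Poisson shot noise, Gaussian read noise, camera
#' offset).  Identical specs (including the seed) generate bit-identical
#' scenes.
#'
#' @slot widthPx,heightPx image size in pixels.
#' @slot pixelSizeNm pixel size in nanometres.
#' @slot organelleClass `"mitochondria"` or `"ER"`.
#' @slot nStructures number of capsules (mitochondria only).
#' @slot tubuleDensity reticular density in (0, 1] (ER only).
#' @slot structureWidthPx structure width in pixels.
#' @slot lengthRangePx capsule length range `c(min, max)` in pixels.
#' @slot markerAmplitude marker photons per footprint pixel (pre-noise).
#' @slot sensorBackground sensor photons per non-organelle pixel (pre-noise).
#' @slot enrichmentFactor pre-noise sensor mean over the organelle footprint
#'   divided by the mean elsewhere (>= 0; 1 = uniform sensor).
#' @slot psfSigmaPx Gaussian PSF sigma in pixels (0 disables blurring).
#' @slot readNoiseSd Gaussian read noise SD (photons).
#' @slot cameraOffset constant camera offset added to every pixel.
#' @slot seed integer RNG seed.
#'
#' @seealso [sceneSpec()], [generateOrganelleScene()]
#' @export
setClass("SceneSpec",
  representation(
    widthPx = "integer",
    heightPx = "integer",
    pixelSizeNm = "numeric",
    organelleClass = "character",
    nStructures = "integer",
    tubuleDensity = "numeric",
    structureWidthPx = "numeric",
    lengthRangePx = "numeric",
    markerAmplitude = "numeric",
    sensorBackground = "numeric",
    enrichmentFactor = "numeric",
    psfSigmaPx = "numeric",
    readNoiseSd = "numeric",
    cameraOffset = "numeric",
    seed = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (object@widthPx < 1L || object@heightPx < 1L)
    msg <- c(msg, "widthPx and heightPx must be positive integers")
  if (object@pixelSizeNm <= 0) msg <- c(msg, "pixelSizeNm must be positive")
  if (!object@organelleClass %in% c("mitochondria", "ER"))
    msg <- c(msg, "organelleClass must be 'mitochondria' or 'ER'")
  if (object@organelleClass == "mitochondria" && object@nStructures < 0L)
    msg <- c(msg, "nStructures must be non-negative")
  if (object@organelleClass == "ER" &&
      (object@tubuleDensity <= 0 || object@tubuleDensity > 1))
    msg <- c(msg, "tubuleDensity must lie in (0, 1]")
  if (object@structureWidthPx <= 0)
    msg <- c(msg, "structureWidthPx must be positive")
  if (length(object@lengthRangePx) != 2L || any(object@lengthRangePx <= 0) ||
      object@lengthRangePx[1] > object@lengthRangePx[2])
    msg <- c(msg, "lengthRangePx must be c(min, max) with 0 < min <= max")
  if (object@markerAmplitude <= 0) msg <- c(msg, "markerAmplitude must be positive")
  if (object@sensorBackground <= 0) msg <- c(msg, "sensorBackground must be positive")
  if (object@enrichmentFactor < 0) msg <- c(msg, "enrichmentFactor must be >= 0")
  if (object@psfSigmaPx < 0) msg <- c(msg, "psfSigmaPx must be >= 0")
  if (object@readNoiseSd < 0) msg <- c(msg, "readNoiseSd must be >= 0")
  if (object@cameraOffset < 0) msg <- c(msg, "cameraOffset must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic scene
#'
#' The noiseless truth behind a generated scene: the organelle footprint,
#' the ideal (pre-PSF) photon-mean rasters, and the post-PSF Poisson-mean
#' rasters actually sampled from.  The pre-PSF sensor raster satisfies the
#' enrichment identity exactly: its mean over the footprint divided by its
#' mean elsewhere equals the spec's enrichment factor.
#'
#' @slot organelleMask logical matrix, TRUE on the organelle footprint.
#' @slot expectedMarker,expectedSensor pre-PSF photon-mean rasters.
#' @slot meanMarker,meanSensor post-PSF Poisson-mean rasters (what the shot
#'   noise is drawn from; excludes read noise and offset).
#'
#' @seealso [generateOrganelleScene()]
#' @export
setClass("GroundTruth",
  representation(
    organelleMask = "matrix",
    expectedMarker = "matrix",
    expectedSensor = "matrix",
    meanMarker = "matrix",
    meanSensor = "matrix"
  )
)

#' Specification of a synthetic decay time-lapse experiment
#'
#' Describes a set of per-cell TIRF footprint intensity traces: a flat
#' pre-stimulation window, then (from treatment time 0) a mono-exponential
#' decay toward a plateau, with Gaussian measurement noise, a constant
#' background, and log-normal baseline jitter across cells.
#'
#' @slot nPreFrames,nPostFrames frames before / from treatment time 0.
#' @slot frameIntervalS frame interval in seconds.
#' @slot baselineIntensity population mean pre-stimulation intensity
#'   (background-free, arbitrary units).
#' @slot rateConstantPerS first-order decay rate constant k (1/s); 0 gives
#'   constant expectation.
#' @slot plateauFraction asymptotic fraction of baseline remaining, in
#'   \[0, 1\]; 1 is equivalent to k = 0.
#' @slot noiseSdFraction Gaussian noise SD as a fraction of the cell's
#'   baseline.
#' @slot background constant additive background.
#' @slot nCells,nExperiments cells per experiment / number of experiments.
#' @slot baselineJitterSdlog SD (log scale) of the log-normal per-cell
#'   baseline jitter; default 0.2 (about 20\%).
#' @slot seed integer RNG seed.
#'
#' @seealso [decaySeriesSpec()], [generateDecaySeries()]
#' @export
setClass("DecaySeriesSpec",
  representation(
    nPreFrames = "integer",
    nPostFrames = "integer",
    frameIntervalS = "numeric",
    baselineIntensity = "numeric",
    rateConstantPerS = "numeric",
    plateauFraction = "numeric",
    noiseSdFraction = "numeric",
    background = "numeric",
    nCells = "integer",
    nExperiments = "integer",
    baselineJitterSdlog = "numeric",
    seed = "integer"
  )
)

setValidity("DecaySeriesSpec", function(object) {
  msg <- character()
  if (object@nPreFrames < 1L)
    msg <- c(msg, "nPreFrames must be >= 1 (pre-stimulation normalization is undefined otherwise)")
  if (object@nPostFrames < 1L) msg <- c(msg, "nPostFrames must be >= 1")
  if (object@frameIntervalS <= 0) msg <- c(msg, "frameIntervalS must be positive")
  if (object@baselineIntensity <= 0) msg <- c(msg, "baselineIntensity must be positive")
  if (object@rateConstantPerS < 0) msg <- c(msg, "rateConstantPerS must be >= 0")
  if (object@plateauFraction < 0 || object@plateauFraction > 1)
    msg <- c(msg, "plateauFraction must lie in [0, 1]")
  if (object@noiseSdFraction < 0) msg <- c(msg, "noiseSdFraction must be >= 0")
  if (object@background < 0) msg <- c(msg, "background must be >= 0")
  if (object@nCells < 1L || object@nExperiments < 1L)
    msg <- c(msg, "nCells and nExperiments must be positive")
  if (object@baselineJitterSdlog < 0)
    msg <- c(msg, "baselineJitterSdlog must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Multi-channel image time-lapse
#'
#' An ordered collection of 2-D intensity rasters, time-major then
#' channel-major (frame 1 channel 1, frame 1 channel 2, frame 2 channel 1,
#' ...), with channel roles and acquisition metadata.
#'
#' @slot frames list of numeric matrices, all the same shape.
#' @slot channels character vector of channel roles (e.g. `"marker"`,
#'   `"sensor"`); its length is the number of channels per timepoint.
#' @slot times numeric vector of frame times in seconds (one per timepoint;
#'   negative = pre-treatment).
#' @slot pixelSizeNm pixel size in nanometres.
#'
#' @seealso [imageStack()], [getFrame()], [readStack()]
#' @export
setClass("ImageStack",
  representation(
    frames = "list",
    channels = "character",
    times = "numeric",
    pixelSizeNm = "numeric"
  )
)

setValidity("ImageStack", function(object) {
  msg <- character()
  nC <- length(object@channels)
  nT <- length(object@times)
  if (nC < 1L) msg <- c(msg, "at least one channel required")
  if (nT < 1L) msg <- c(msg, "at least one timepoint required")
  if (length(object@frames) != nC * nT)
    msg <- c(msg, sprintf("expected %d frames (%d timepoints x %d channels), found %d",
                          nC * nT, nT, nC, length(object@frames)))
  if (length(object@frames)) {
    dims <- vapply(object@frames, function(f) paste(dim(f), collapse = "x"), "")
    if (length(unique(dims)) > 1L)
      msg <- c(msg, "all frames must share the same dimensions")
  }
  if (nT > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Per-cell intensity trace
#'
#' One cell's mean footprint intensity over time, with the background, the
#' pre-stimulation window used for F/F_pre normalization, and the
#' normalized values.  The normalized trace averages to 1 over the
#' pre-stimulation window by construction.
#'
#' @slot cellId,experimentId identifiers.
#' @slot timesS strictly increasing frame times in seconds (negative =
#'   pre-treatment).
#' @slot raw raw mean intensities, one per time point.
#' @slot background scalar background subtracted before normalization.
#' @slot preWindow integer indices of the pre-stimulation frames.
#' @slot normalized background-subtracted intensities divided by their
#'   pre-window mean.
#'
#' @seealso [cellTrace()], [normalizeTrace()], [generateDecaySeries()]
#' @export
setClass("CellTrace",
  representation(
    cellId = "character",
    experimentId = "character",
    timesS = "numeric",
    raw = "numeric",
    background = "numeric",
    preWindow = "integer",
    normalized = "numeric"
  )
)

setValidity("CellTrace", function(object) {
  msg <- character()
  n <- length(object@timesS)
  if (length(object@raw) != n)
    msg <- c(msg, "raw and timesS must have equal length")
  if (n > 1L && any(diff(object@timesS) <= 0))
    msg <- c(msg, "timesS must be strictly increasing")
  if (length(object@preWindow) < 1L)
    msg <- c(msg, "preWindow must be non-empty")
  if (any(object@preWindow < 1L) || any(object@preWindow > n))
    msg <- c(msg, "preWindow indices out of range")
  if (length(object@normalized) == n && n > 0L) {
    m <- mean(object@normalized[object@preWindow])
    if (is.finite(m) && abs(m - 1) > 1e-9)
      msg <- c(msg, "normalized trace must average to 1 over preWindow")
  }
  if (length(msg)) msg else TRUE
})

#' First-order lipid turnover model
#'
#' The copy-number flux calculator: a population of transporter molecules,
#' each completing a fixed number of transfer cycles per second, drains a
#' lipid pool.  Derived quantities are the total flux (molecules/s), the
#' first-order fractional rate constant k = flux / pool (1/s), and the
#' half-life ln(2)/k (s).  A user-supplied `k` may override the chained
#' value (the override is recorded in `kSource`); the chained flux is still
#' reported.
#'
#' @slot copies transporter copies per cell.
#' @slot turnoverPerS transfer cycles per second per molecule.
#' @slot pool lipid molecules per cell.
#' @slot flux derived flux, molecules per second.
#' @slot k fractional rate constant, 1/s.
#' @slot tHalfS half-life, seconds.
#' @slot kSource `"derived"` (k = flux/pool) or `"supplied"`.
#'
#' @seealso [turnoverModel()], [transferFlux()], [rateConstant()], [halfLife()]
#' @export
setClass("TurnoverModel",
  representation(
    copies = "numeric",
    turnoverPerS = "numeric",
    pool = "numeric",
    flux = "numeric",
    k = "numeric",
    tHalfS = "numeric",
    kSource = "character"
  )
)

setValidity("TurnoverModel", function(object) {
  msg <- character()
  if (any(c(object@copies, object@turnoverPerS) < 0))
    msg <- c(msg, "copies and turnoverPerS must be >= 0")
  if (object@pool <= 0) msg <- c(msg, "pool must be positive")
  if (!object@kSource %in% c("derived", "supplied"))
    msg <- c(msg, "kSource must be 'derived' or 'supplied'")
  if (length(msg)) msg else TRUE
})

#' Mono-exponential decay fit
#'
#' Result of fitting f(t) = plateau + (f0 - plateau) exp(-k t) to a
#' normalized post-treatment trace.
#'
#' @slot f0 fitted normalized intensity at t = 0.
#' @slot plateau fitted asymptote.
#' @slot kFit fitted rate constant, 1/s (>= 0).
#' @slot residualRms root-mean-square residual.
#' @slot nPoints number of points fitted.
#' @slot plateauFixed TRUE if the plateau was pinned rather than fitted.
#'
#' @seealso [fitMonoexponential()], [predictDecay()]
#' @export
setClass("DecayFit",
  representation(
    f0 = "numeric",
    plateau = "numeric",
    kFit = "numeric",
    residualRms = "numeric",
    nPoints = "integer",
    plateauFixed = "logical"
  )
)

setValidity("DecayFit", function(object) {
  msg <- character()
  if (object@kFit < 0) msg <- c(msg, "kFit must be >= 0")
  if (object@residualRms < 0) msg <- c(msg, "residualRms must be >= 0")
  if (length(msg)) msg else TRUE
})
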