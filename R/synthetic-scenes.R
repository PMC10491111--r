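#' Specify a synthetic organelle scene
#'
#' Constructor for [SceneSpec-class].  Defaults describe a realistic
#' confocal field: a ~27 um field of view at 140 nm pixels, mitochondria
#' ~0.7 um wide (5 px) and 2--6 um long, photon amplitudes in the hundreds
#' (marker) and tens (sensor background), a 1-pixel PSF sigma, and sCMOS-like
#' read noise and offset.
#'
#' @param widthPx,heightPx image size in pixels.
#' @param pixelSizeNm pixel size, nm.
#' @param organelleClass `"mitochondria"` or `"ER"`.
#' @param nStructures capsule count (mitochondria).
#' @param tubuleDensity reticular density in (0, 1] (ER).
#' @param structureWidthPx structure width, pixels; `NULL` (default) picks a
#'   class-appropriate width: 5 px (~0.7 um) for mitochondria, 2 px
#'   (~280 nm, the diffraction-limited apparent width of an ER tubule) for
#'   ER.
#' @param lengthRangePx capsule length range `c(min, max)`, pixels.
#' @param markerAmplitude marker photons on the footprint.
#' @param sensorBackground sensor photons off the footprint.
#' @param enrichmentFactor pre-noise sensor enrichment on the footprint
#'   (1 = uniform).
#' @param psfSigmaPx Gaussian PSF sigma, pixels.
#' @param readNoiseSd Gaussian read noise SD, photons.
#' @param cameraOffset constant camera offset.
#' @param seed integer RNG seed.
#' @return a [SceneSpec-class].
#' @examples
#' sceneSpec(seed = 7)
#' sceneSpec(organelleClass = "ER", tubuleDensity = 0.5, seed = 11)
#' @export
sceneSpec <- function(widthPx = 192, heightPx = 192, pixelSizeNm = 140,
                      organelleClass = c("mitochondria", "ER"),
                      nStructures = 12, tubuleDensity = 0.5,
                      structureWidthPx = NULL, lengthRangePx = c(15, 40),
                      markerAmplitude = 200, sensorBackground = 50,
                      enrichmentFactor = 3, psfSigmaPx = 1,
                      readNoiseSd = 2, cameraOffset = 100, seed = 1) {
  organelleClass <- match.arg(organelleClass)
  if (is.null(structureWidthPx))
    structureWidthPx <- if (organelleClass == "mitochondria") 5 else 2
  new("SceneSpec",
      widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
      pixelSizeNm = as.numeric(pixelSizeNm), organelleClass = organelleClass,
      nStructures = as.integer(nStructures),
      tubuleDensity = as.numeric(tubuleDensity),
      structureWidthPx = as.numeric(structureWidthPx),
      lengthRangePx = as.numeric(lengthRangePx),
      markerAmplitude = as.numeric(markerAmplitude),
      sensorBackground = as.numeric(sensorBackground),
      enrichmentFactor = as.numeric(enrichmentFactor),
      psfSigmaPx = as.numeric(psfSigmaPx),
      readNoiseSd = as.numeric(readNoiseSd),
      cameraOffset = as.numeric(cameraOffset),
      seed = as.integer(seed))
}

# Paint one capsule (thick line segment) onto a logical raster; returns the
# capsule's own footprint.
capsuleFootprint <- function(ny, nx, cy, cx, angle, len, width) {
  hx <- cos(angle) * len / 2
  hy <- sin(angle) * len / 2
  p1 <- c(cy - hy, cx - hx)
  p2 <- c(cy + hy, cx + hx)
  rad <- width / 2
  y0 <- max(1L, floor(min(p1[1], p2[1]) - rad - 1))
  y1 <- min(ny, ceiling(max(p1[1], p2[1]) + rad + 1))
  x0 <- max(1L, floor(min(p1[2], p2[2]) - rad - 1))
  x1 <- min(nx, ceiling(max(p1[2], p2[2]) + rad + 1))
  out <- matrix(FALSE, ny, nx)
  if (y0 > y1 || x0 > x1) return(out)
  ys <- y0:y1; xs <- x0:x1
  Y <- matrix(ys, length(ys), length(xs))
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  d <- c(p2[1] - p1[1], p2[2] - p1[2])
  dd <- sum(d^2)
  tt <- if (dd > 0) pmin(1, pmax(0, ((Y - p1[1]) * d[1] + (X - p1[2]) * d[2]) / dd)) else 0
  dist2 <- (Y - (p1[1] + tt * d[1]))^2 + (X - (p1[2] + tt * d[2]))^2
  out[cbind(as.vector(row(Y) + y0 - 1L), as.vector(col(X) + x0 - 1L))] <-
    as.vector(dist2 <= rad^2)
  out
}

# Mitochondria: randomly placed/oriented capsules, rejection-sampled so a
# new capsule overlaps the existing footprint by < 10% of its own area.
drawMitochondria <- function(spec) {
  ny <- spec@heightPx; nx <- spec@widthPx
  mask <- matrix(FALSE, ny, nx)
  for (i in seq_len(spec@nStructures)) {
    for (attempt in seq_len(50L)) {
      cy <- runif(1, 1, ny)
      cx <- runif(1, 1, nx)
      ang <- runif(1, 0, pi)
      len <- runif(1, spec@lengthRangePx[1], spec@lengthRangePx[2])
      fp <- capsuleFootprint(ny, nx, cy, cx, ang, len, spec@structureWidthPx)
      a <- sum(fp)
      if (a == 0L) next
      if (sum(fp & mask) < 0.1 * a) break
    }
    mask <- mask | fp
  }
  mask
}

# ER: skeleton of a random planar partition (nearest-seed region
# boundaries), dilated to the structure width.  tubuleDensity scales the
# number of partition seeds and hence the mesh density.
drawER <- function(spec) {
  ny <- spec@heightPx; nx <- spec@widthPx
  nSeeds <- max(4L, as.integer(round(spec@tubuleDensity * ny * nx / 256)))
  sy <- runif(nSeeds, 1, ny)
  sx <- runif(nSeeds, 1, nx)
  Y <- matrix(seq_len(ny), ny, nx)
  X <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  best <- matrix(Inf, ny, nx)
  lab <- matrix(0L, ny, nx)
  for (s in seq_len(nSeeds)) {
    d2 <- (Y - sy[s])^2 + (X - sx[s])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    lab[upd] <- s
  }
  skel <- matrix(FALSE, ny, nx)
  skel[-ny, ] <- skel[-ny, ] | (lab[-ny, ] != lab[-1, ])
  skel[, -nx] <- skel[, -nx] | (lab[, -nx] != lab[, -1])
  d <- EBImage::distmap(1 - skel)
  matrix(as.numeric(d) <= spec@structureWidthPx / 2, ny, nx)
}

#' Generate a two-channel synthetic organelle scene with ground truth
#'
#' Draws the organelle footprint (capsule-shaped mitochondria or an
#' ER-like reticular network), builds the ideal marker raster (amplitude on
#' the footprint, zero elsewhere) and sensor raster (background times the
#' enrichment factor on the footprint, background elsewhere), convolves
#' both with a Gaussian PSF, and samples Poisson shot noise plus Gaussian
#' read noise plus a constant camera offset.  All randomness is driven by
#' the spec's seed; identical specs give bit-identical scenes.
#'
#' @param spec a [SceneSpec-class].
#' @return list with elements `marker` and `sensor` (numeric matrices) and
#'   `truth` (a [GroundTruth-class]).
#' @examples
#' scn <- generateOrganelleScene(sceneSpec(seed = 7))
#' mean(scn$truth@expectedSensor[scn$truth@organelleMask]) /
#'   mean(scn$truth@expectedSensor[!scn$truth@organelleMask])
#' @export
generateOrganelleScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    mask <- if (spec@organelleClass == "mitochondria") {
      if (spec@nStructures == 0L)
        matrix(FALSE, spec@heightPx, spec@widthPx)
      else drawMitochondria(spec)
    } else drawER(spec)
    if (spec@organelleClass == "mitochondria" && spec@nStructures > 0L &&
        !any(mask))
      stop("generated organelle footprint has zero area despite nStructures > 0")

    expectedMarker <- matrix(0, spec@heightPx, spec@widthPx)
    expectedMarker[mask] <- spec@markerAmplitude
    expectedSensor <- matrix(spec@sensorBackground, spec@heightPx, spec@widthPx)
    expectedSensor[mask] <- spec@sensorBackground * spec@enrichmentFactor

    meanMarker <- gaussianBlur(expectedMarker, spec@psfSigmaPx)
    meanSensor <- gaussianBlur(expectedSensor, spec@psfSigmaPx)

    sampleChannel <- function(lambda) {
      n <- length(lambda)
      shot <- matrix(rpois(n, pmax(lambda, 0)), nrow(lambda), ncol(lambda))
      read <- if (spec@readNoiseSd > 0)
        matrix(rnorm(n, 0, spec@readNoiseSd), nrow(lambda), ncol(lambda))
      else 0
      shot + read + spec@cameraOffset
    }
    marker <- sampleChannel(meanMarker)
    sensor <- sampleChannel(meanSensor)

    truth <- new("GroundTruth", organelleMask = mask,
                 expectedMarker = expectedMarker,
                 expectedSensor = expectedSensor,
                 meanMarker = meanMarker, meanSensor = meanSensor)
    list(marker = marker, sensor = sensor, truth = truth)
  })
}

#' Specify a synthetic decay time-lapse experiment
#'
#' Constructor for [DecaySeriesSpec-class].  Defaults mirror a typical
#' TIRF PI4P-turnover assay: 30-s frames, a 4-frame pre-stimulation window,
#' 30 post-treatment frames, and 2\% measurement noise.
#'
#' @param nPreFrames,nPostFrames frames before / from treatment time 0.
#' @param frameIntervalS frame interval, s.
#' @param baselineIntensity mean pre-stimulation intensity.
#' @param rateConstantPerS decay rate constant k, 1/s.
#' @param plateauFraction asymptotic remaining fraction in \[0, 1\].
#' @param noiseSdFraction Gaussian noise SD as a fraction of baseline.
#' @param background constant additive background.
#' @param nCells,nExperiments cells per experiment / experiments.
#' @param baselineJitterSdlog log-normal baseline jitter SD (log scale).
#' @param seed integer RNG seed.
#' @return a [DecaySeriesSpec-class].
#' @export
decaySeriesSpec <- function(nPreFrames = 4, nPostFrames = 30,
                            frameIntervalS = 30, baselineIntensity = 1000,
                            rateConstantPerS = 0.001, plateauFraction = 0,
                            noiseSdFraction = 0.02, background = 100,
                            nCells = 12, nExperiments = 3,
                            baselineJitterSdlog = 0.2, seed = 1) {
  new("DecaySeriesSpec",
      nPreFrames = as.integer(nPreFrames), nPostFrames = as.integer(nPostFrames),
      frameIntervalS = as.numeric(frameIntervalS),
      baselineIntensity = as.numeric(baselineIntensity),
      rateConstantPerS = as.numeric(rateConstantPerS),
      plateauFraction = as.numeric(plateauFraction),
      noiseSdFraction = as.numeric(noiseSdFraction),
      background = as.numeric(background),
      nCells = as.integer(nCells), nExperiments = as.integer(nExperiments),
      baselineJitterSdlog = as.numeric(baselineJitterSdlog),
      seed = as.integer(seed))
}

#' Generate per-cell decay traces grouped by experiment
#'
#' Each cell's raw trace has expectation
#' `background + baseline_c * [1 pre-treatment; plateau + (1 - plateau)
#' exp(-k t) from t = 0]` with i.i.d. Gaussian noise of SD
#' `noiseSdFraction * baseline_c`.  Per-cell baselines are jittered
#' log-normally (mean-preserving) around the population baseline.  Frame
#' times run from `-nPreFrames * dt` to `(nPostFrames - 1) * dt`; treatment
#' is at time 0.
#'
#' @param spec a [DecaySeriesSpec-class].
#' @return list of [CellTrace-class], ordered experiment-major.
#' @examples
#' traces <- generateDecaySeries(decaySeriesSpec(nCells = 2, nExperiments = 2))
#' traces[[1]]
#' @export
generateDecaySeries <- function(spec) {
  stopifnot(is(spec, "DecaySeriesSpec"))
  validObject(spec)
  dt <- spec@frameIntervalS
  times <- c(-(spec@nPreFrames:1), 0:(spec@nPostFrames - 1L)) * dt
  post <- times >= 0
  shape <- ifelse(post,
                  spec@plateauFraction + (1 - spec@plateauFraction) *
                    exp(-spec@rateConstantPerS * pmax(times, 0)),
                  1)
  preWindow <- seq_len(spec@nPreFrames)
  sdl <- spec@baselineJitterSdlog
  withSeed(spec@seed, {
    traces <- vector("list", spec@nExperiments * spec@nCells)
    i <- 0L
    for (e in seq_len(spec@nExperiments)) {
      for (cc in seq_len(spec@nCells)) {
        base <- spec@baselineIntensity * exp(rnorm(1, -sdl^2 / 2, sdl))
        raw <- spec@background + base * shape +
          rnorm(length(times), 0, spec@noiseSdFraction * base)
        i <- i + 1L
        traces[[i]] <- cellTrace(
          cellId = sprintf("e%02d_c%02d", e, cc),
          experimentId = sprintf("e%02d", e),
          timesS = times, raw = raw,
          background = spec@background, preWindow = preWindow)
      }
    }
    traces
  })
}

#' Idealized contact-site recruitment curve
#'
#' Mono-exponential rise of biosensor enrichment after recruiter addition:
#' `enrichment(t) = 1 + (maxEnrichment - 1) * (1 - exp(-ln(2) t / tHalfS))`
#' for `t >= 0`, and 1 before.  Used to fold a known recruitment kinetic
#' into synthetic sensor channels.
#'
#' @param tHalfS half-rise time, s (> 0).
#' @param maxEnrichment asymptotic enrichment (>= 1).
#' @param times numeric vector of times, s.
#' @return numeric vector of enrichment factors, same length as `times`.
#' @examples
#' generateRecruitmentTrace(60, 3, c(0, 60, 1e6))
#' @export
generateRecruitmentTrace <- function(tHalfS, maxEnrichment, times) {
  if (tHalfS <= 0) stop("tHalfS must be positive")
  if (maxEnrichment < 1) stop("maxEnrichment must be >= 1")
  if (length(times) == 0L) return(numeric(0))
  ifelse(times >= 0,
         1 + (maxEnrichment - 1) * (1 - exp(-log(2) * times / tHalfS)),
         1)
}

#' Construct a cell trace
#'
#' Builds a [CellTrace-class], computing the F/F_pre-normalized values via
#' [normalizeTrace()].
#'
#' @param cellId,experimentId identifiers.
#' @param timesS strictly increasing frame times, s.
#' @param raw raw mean intensities.
#' @param background scalar background.
#' @param preWindow integer indices of pre-stimulation frames; default =
#'   all frames with `timesS < 0`.
#' @return a [CellTrace-class].
#' @export
cellTrace <- function(cellId, experimentId, timesS, raw, background = 0,
                      preWindow = which(timesS < 0)) {
  normalized <- normalizeTrace(raw, background = background,
                               preWindow = preWindow)
  new("CellTrace", cellId = as.character(cellId),
      experimentId = as.character(experimentId),
      timesS = as.numeric(timesS), raw = as.numeric(raw),
      background = as.numeric(background),
      preWindow = as.integer(preWindow), normalized = normalized)
}

#' Construct an image stack
#'
#' @param frames list of numeric matrices, time-major then channel-major.
#' @param channels character vector of channel roles.
#' @param times frame times in seconds, one per timepoint.
#' @param pixelSizeNm pixel size, nm.
#' @return an [ImageStack-class].
#' @export
imageStack <- function(frames, channels, times, pixelSizeNm = 140) {
  new("ImageStack", frames = frames, channels = as.character(channels),
      times = as.numeric(times), pixelSizeNm = as.numeric(pixelSizeNm))
}
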