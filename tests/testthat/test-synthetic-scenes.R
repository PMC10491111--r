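test_that("scene generation is deterministic given the spec and restores the caller's RNG state", {
  spec <- sceneSpec(seed = 7, nStructures = 12, enrichmentFactor = 3,
                    psfSigmaPx = 1.2, readNoiseSd = 2)
  set.seed(999); before <- runif(1)
  set.seed(999)
  s1 <- generateOrganelleScene(spec)
  after <- runif(1)
  s2 <- generateOrganelleScene(spec)
  expect_identical(s1$marker, s2$marker)
  expect_identical(s1$sensor, s2$sensor)
  expect_identical(s1$truth@organelleMask, s2$truth@organelleMask)
  expect_equal(before, after)  # caller RNG stream untouched

  s3 <- generateOrganelleScene(sceneSpec(seed = 8))
  expect_false(identical(s1$marker, s3$marker))
})

test_that("empty scenes and uniform sensors behave as degenerate cases", {
  s <- generateOrganelleScene(sceneSpec(nStructures = 0, seed = 1,
                                        psfSigmaPx = 0))
  expect_false(any(s$truth@organelleMask))
  expect_true(all(s$truth@expectedSensor == 50))

  u <- generateOrganelleScene(sceneSpec(enrichmentFactor = 1, seed = 2))
  g <- u$truth@organelleMask
  es <- u$truth@expectedSensor
  expect_equal(mean(es[g]) / mean(es[!g]), 1.0)
})

test_that("pre-PSF sensor enrichment equals the spec factor exactly", {
  for (E in c(0, 1, 2.5, 5)) {
    s <- generateOrganelleScene(sceneSpec(enrichmentFactor = E, seed = 3))
    g <- s$truth@organelleMask
    es <- s$truth@expectedSensor
    expect_equal(mean(es[g]) / mean(es[!g]), E, tolerance = 1e-9)
  }
})

test_that("sampled intensities converge to the Poisson mean raster", {
  # uniform scene: every pixel shares one rate, so draws across seeds are
  # i.i.d. replicates of the same per-pixel model
  B <- 50; n <- 200
  spec0 <- function(seed) sceneSpec(widthPx = 24, heightPx = 24,
                                    nStructures = 0, sensorBackground = B,
                                    psfSigmaPx = 0, readNoiseSd = 0,
                                    cameraOffset = 0, seed = seed)
  acc <- matrix(0, 24, 24)
  for (s in seq_len(n)) acc <- acc + generateOrganelleScene(spec0(s))$sensor
  perPixelMean <- acc / n
  se <- sqrt(B / n)
  fracWithin <- mean(abs(perPixelMean - B) <= 3 * se)
  expect_gte(fracWithin, 0.99)

  # structured scene: spatial aggregate of (sample - offset) matches the
  # Poisson mean raster
  s <- generateOrganelleScene(sceneSpec(seed = 4))
  expect_equal(mean(s$sensor - 100), mean(s$truth@meanSensor),
               tolerance = 0.02)
})

test_that("decay series have the stated expectation structure", {
  # k = 0: post/pre expectation ratio is 1
  tr0 <- generateDecaySeries(decaySeriesSpec(rateConstantPerS = 0,
                                             noiseSdFraction = 0, seed = 1,
                                             nCells = 2, nExperiments = 1))
  for (tr in tr0) expect_equal(unique(tr@normalized), 1)

  # plateau 1 is expectation-identical to k = 0
  trP <- generateDecaySeries(decaySeriesSpec(plateauFraction = 1,
                                             rateConstantPerS = 0.01,
                                             noiseSdFraction = 0, seed = 1,
                                             nCells = 2, nExperiments = 1))
  for (i in seq_along(trP))
    expect_equal(trP[[i]]@normalized, tr0[[i]]@normalized)

  # noiseless decay normalizes to the exact exponential; baseline jitter
  # cancels under F/F_pre
  trD <- generateDecaySeries(decaySeriesSpec(rateConstantPerS = 0.001,
                                             noiseSdFraction = 0, seed = 2,
                                             nCells = 1, nExperiments = 1))[[1]]
  post <- trD@timesS >= 0
  expect_equal(trD@normalized[post], exp(-0.001 * trD@timesS[post]),
               tolerance = 1e-12)
  expect_equal(trD@normalized[trD@timesS == 690], exp(-0.69))

  expect_error(decaySeriesSpec(nPreFrames = 0), "nPreFrames")

  # determinism
  a <- generateDecaySeries(decaySeriesSpec(seed = 5, nCells = 3))
  b <- generateDecaySeries(decaySeriesSpec(seed = 5, nCells = 3))
  expect_identical(lapply(a, slot, "raw"), lapply(b, slot, "raw"))
})

test_that("fitting recovers the generator's rate constant from noisy traces", {
  traces <- generateDecaySeries(decaySeriesSpec(rateConstantPerS = 0.001,
                                                noiseSdFraction = 0.02,
                                                nPostFrames = 30,
                                                frameIntervalS = 30,
                                                nCells = 12, nExperiments = 3,
                                                seed = 11))
  ks <- vapply(traces, function(tr) {
    post <- tr@timesS >= 0
    fitMonoexponential(tr@timesS[post], tr@normalized[post])@kFit
  }, numeric(1))
  expect_lt(abs(median(ks) / 0.001 - 1), 0.10)
})

test_that("recruitment traces follow the saturating exponential", {
  expect_equal(generateRecruitmentTrace(60, 3, 0), 1.0)
  expect_equal(generateRecruitmentTrace(60, 3, 1e9), 3.0)
  expect_equal(generateRecruitmentTrace(60, 3, 60), 1 + (3 - 1) / 2)
  expect_equal(generateRecruitmentTrace(60, 3, -10), 1.0)
  expect_identical(generateRecruitmentTrace(60, 3, numeric(0)), numeric(0))
  expect_error(generateRecruitmentTrace(0, 3, 1), "positive")
  expect_error(generateRecruitmentTrace(60, 0.5, 1), ">= 1")
})
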