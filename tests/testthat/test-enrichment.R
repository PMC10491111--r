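test_that("cell footprint segmentation finds a bright disk and rejects degenerate input", {
  n <- 64
  Y <- matrix(seq_len(n), n, n); X <- t(Y)
  disk <- (Y - 32)^2 + (X - 32)^2 <= 20^2
  img <- matrix(10, n, n); img[disk] <- 100
  fp <- cellFootprint(img, "otsu")
  expect_gte(maskIoU(maskRaster(fp), disk), 0.9)

  full <- cellFootprint(img, "user_roi", roi = matrix(TRUE, n, n))
  expect_true(all(maskRaster(full)))

  expect_error(cellFootprint(matrix(5, 16, 16), "otsu"), "ROI")
  expect_error(cellFootprint(img, "user_roi", roi = matrix(FALSE, n, n)), "empty")
})

test_that("normalization to the cell mean is exact and scale-invariant", {
  n <- 16
  fp <- matrix(TRUE, n, n)
  const <- matrix(4, n, n)
  expect_equal(normalizeToCellMean(const, fp), matrix(1, n, n))

  img <- randomTestImage(n, 4)
  norm <- normalizeToCellMean(img, fp)
  expect_equal(mean(norm[fp]), 1, tolerance = 1e-9)
  expect_equal(normalizeToCellMean(5 * img, fp), norm)

  half <- matrix(1, n, n); half[, 1:(n / 2)] <- 2
  nh <- normalizeToCellMean(half, fp)
  expect_equal(sort(unique(as.vector(nh))), c(2 / 3, 4 / 3))

  expect_error(normalizeToCellMean(img - 1e9, fp), "positive")
})

test_that("enrichment ratio is exact on constructed scenes and scale-invariant", {
  n <- 32
  msk <- matrix(FALSE, n, n); msk[10:20, 10:20] <- TRUE
  uni <- matrix(6, n, n)
  expect_equal(enrichmentRatio(uni, msk)$enrichment, 1.0)

  three <- matrix(1, n, n); three[msk] <- 3
  r <- enrichmentRatio(three, msk)
  expect_equal(r$enrichment, 3.0)
  expect_equal(r$mean_inside, 3); expect_equal(r$mean_outside, 1)

  for (aa in c(0.1, 2, 40))
    expect_equal(enrichmentRatio(aa * three, msk)$enrichment, 3.0)

  # partition identity: |in| mi + |out| mo = |fp| cell_mean
  img <- randomTestImage(n, 5)
  fp <- matrix(TRUE, n, n); fp[1:4, ] <- FALSE
  rr <- enrichmentRatio(img, msk, fp)
  lhs <- sum(msk & fp) * rr$mean_inside + sum(fp & !msk) * rr$mean_outside
  expect_equal(lhs / (sum(fp) * rr$cell_mean), 1, tolerance = 1e-6)

  expect_error(enrichmentRatio(uni, matrix(FALSE, n, n)), "inside")
  expect_error(enrichmentRatio(uni, matrix(TRUE, n, n)), "outside")
})

test_that("measured enrichment through mask + ratio tracks the generator factor", {
  # offset-subtracted sensor, wavelet mask from the marker channel
  med <- median(vapply(1:8, function(s) {
    scn <- generateOrganelleScene(sceneSpec(seed = 200 + s, enrichmentFactor = 3))
    msk <- makeOrganelleMask(scn$marker, scaleProfile("mitochondria"), airyDisc())
    enrichmentRatio(scn$sensor - 100, msk)$enrichment
  }, numeric(1)))
  # PSF blur plus the 2-px mask dilation dilute the ratio toward 1; the
  # measured value sits well above 1 and scales with the factor
  expect_gt(med, 2)
  expect_lt(med, 3)

  medNoBlur <- median(vapply(1:8, function(s) {
    scn <- generateOrganelleScene(sceneSpec(seed = 300 + s, enrichmentFactor = 3,
                                            psfSigmaPx = 0, readNoiseSd = 0,
                                            cameraOffset = 0))
    g <- scn$truth@organelleMask
    enrichmentRatio(scn$truth@expectedSensor, g)$enrichment
  }, numeric(1)))
  expect_equal(medNoBlur, 3.0, tolerance = 1e-9)
})

test_that("enrichment time courses follow the stack frame by frame", {
  scn <- generateOrganelleScene(sceneSpec(widthPx = 96, heightPx = 96,
                                          nStructures = 6, seed = 9))
  # static scene repeated: series exactly constant
  stk <- imageStack(rep(list(scn$marker, scn$sensor), 5),
                    channels = c("marker", "sensor"), times = (0:4) * 30)
  tc <- enrichmentTimecourse(stk)
  expect_equal(nrow(tc), 5)
  expect_equal(length(unique(tc$enrichment)), 1L)

  one <- imageStack(list(scn$marker, scn$sensor), c("marker", "sensor"), 0)
  expect_equal(nrow(enrichmentTimecourse(one)), 1)

  # recruitment kinetic folded into a noiseless sensor channel is
  # recovered as a monotone non-decreasing series
  g <- scn$truth@organelleMask
  times <- seq(0, 300, by = 60)
  E <- generateRecruitmentTrace(90, 4, times)
  frames <- unlist(lapply(E, function(e) {
    sens <- matrix(50, 96, 96); sens[g] <- 50 * e
    list(scn$truth@expectedMarker, sens)
  }), recursive = FALSE)
  stk2 <- imageStack(frames, c("marker", "sensor"), times)
  tc2 <- enrichmentTimecourse(stk2)
  expect_true(all(diff(tc2$enrichment) >= 0))

  # pre-treatment normalization: mean over pre frames is 1
  stk3 <- imageStack(rep(list(scn$marker, scn$sensor), 4),
                     channels = c("marker", "sensor"),
                     times = c(-60, -30, 0, 30))
  tc3 <- enrichmentTimecourse(stk3)
  expect_equal(mean(tc3$normalized_enrichment[tc3$time_s < 0]), 1)
})
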