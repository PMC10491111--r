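test_that("Airy radius follows the Rayleigh formula", {
  a <- airyDisc(670, 1.45, 140)
  expect_equal(radiusPx(a), 0.61 * 670 / 1.45 / 140)
  expect_error(airyDisc(-1, 1.45, 140), "positive")
})

test_that("Gaussian filtering preserves constants and affine ramps, and matches a dense-convolution oracle on a delta image", {
  a <- airyDisc(pixelSizeNm = 0.61 * 670 / 1.45)  # radius exactly 1 px
  const <- matrix(7, 12, 12)
  fs <- gaussianFilteredStack(const, a, c(1, 2))
  expect_equal(fs[[1]], const)
  expect_equal(fs[[2]], const)

  # delta at the center reproduces the normalized discrete Gaussian kernel
  delta <- matrix(0, 9, 9); delta[5, 5] <- 1
  got <- gaussianFilteredStack(delta, a, 1)[[1]]
  k1 <- exp(-(-4:4)^2 / 2); k1 <- k1 / sum(k1)
  expect_equal(got, outer(k1, k1), tolerance = 1e-12)

  # a linear ramp is preserved in the interior under reflective boundaries
  ramp <- matrix(rep(seq_len(32), each = 32), 32, 32)
  f <- gaussianFilteredStack(ramp, a, 1)[[1]]
  interior <- 6:27
  expect_equal(f[interior, interior], ramp[interior, interior], tolerance = 1e-9)

  bad <- const; bad[3, 4] <- NA
  expect_error(gaussianFilteredStack(bad, a, 1), "y=3, x=4")
})

test_that("wavelet planes are consecutive differences with the telescoping identity", {
  img <- randomTestImage(16, 1)
  a <- airyDisc()
  fsER <- gaussianFilteredStack(img, a, c(1, 2))
  fsMito <- gaussianFilteredStack(img, a, 1:4)
  expect_length(waveletImages(fsER), 1L)
  expect_length(waveletImages(fsMito), 3L)
  expect_error(waveletImages(fsER[1]), "at least 2")

  ws <- waveletImages(fsMito)
  expect_equal(Reduce(`+`, ws), fsMito[[1]] - fsMito[[4]], tolerance = 1e-9)

  same <- list(img, img)
  expect_equal(waveletImages(same)[[1]], matrix(0, 16, 16))
})

test_that("wavelet product clamps negatives and geometric mean restores intensity units", {
  w <- list(matrix(1, 2, 2), matrix(4, 2, 2), matrix(16, 2, 2))
  expect_equal(waveletProduct(w), matrix(4, 2, 2))
  expect_equal(waveletProduct(w, "raw_product"), matrix(64, 2, 2))

  wneg <- list(matrix(c(-1, 2, 3, 4), 2, 2), matrix(5, 2, 2))
  expect_equal(waveletProduct(wneg, "raw_product")[1, 1], 0)

  single <- list(matrix(c(-2, 3, 0, 1), 2, 2))
  expect_equal(waveletProduct(single), pmax(single[[1]], 0))
  expect_equal(waveletProduct(single, "raw_product"), pmax(single[[1]], 0))

  expect_error(waveletProduct(list(matrix(0, 2, 2), matrix(0, 3, 3))), "mismatch")
})

test_that("thresholding uses the population SD of the original image and degrades gracefully", {
  img <- randomTestImage(16, 2)
  prodImg <- waveletProduct(waveletImages(gaussianFilteredStack(img, airyDisc(), c(1, 2))))
  msk <- thresholdMask(prodImg, img, 0.5)
  n <- length(img)
  expect_equal(thresholdValue(msk), 0.5 * sqrt(mean((img - mean(img))^2)))

  const <- matrix(3, 8, 8)
  mc <- thresholdMask(matrix(0, 8, 8), const, 0.5)
  expect_false(any(maskRaster(mc)))
  expect_equal(thresholdValue(mc), 0)

  expect_error(thresholdMask(prodImg, img, -1), "positive")
  expect_error(thresholdMask(prodImg, img[1:4, 1:4]), "shape")
})

test_that("dilation uses the discrete Euclidean disk and is monotone", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  expect_identical(dilateMask(m, 0), m)
  expect_equal(sum(dilateMask(m, 2)), 13)  # offsets with dy^2+dx^2 <= 4
  expect_equal(sum(dilateMask(m, 1)), 5)

  allTrue <- matrix(TRUE, 6, 6)
  expect_identical(dilateMask(allTrue, 3), allTrue)

  set.seed(3)
  rnd <- matrix(runif(81) < 0.1, 9, 9)
  d1 <- dilateMask(rnd, 1); d2 <- dilateMask(rnd, 2)
  expect_true(all(d1[rnd]))      # dilation covers the input
  expect_true(all(d2[d1]))       # larger radius covers smaller
  expect_error(dilateMask(rnd, -1), "non-negative")
})

test_that("full mask pipeline matches the brute-force oracle bit-for-bit on small images", {
  a <- airyDisc()
  profiles <- list(scaleProfile("ER"), scaleProfile("mitochondria"))
  for (seed in 1:6) {
    img <- randomTestImage(16, seed)
    for (p in profiles) {
      got <- maskRaster(makeOrganelleMask(img, p, a))
      want <- oracleMask(img, p@scaleMultiples, radiusPx(a),
                         p@thresholdSdFactor, p@dilationPx,
                         p@productNormalization)
      expect_identical(got, want)
    }
  }
})

test_that("masks are invariant to affine intensity transforms under geometric-mean normalization", {
  scn <- generateOrganelleScene(sceneSpec(widthPx = 96, heightPx = 96,
                                          nStructures = 6, seed = 5))
  p <- scaleProfile("mitochondria")
  a <- airyDisc()
  ref <- maskRaster(makeOrganelleMask(scn$marker, p, a))
  for (aa in c(0.5, 2, 10)) for (bb in c(0, 100)) {
    got <- maskRaster(makeOrganelleMask(aa * scn$marker + bb, p, a))
    expect_identical(got, ref)
  }
})

test_that("mask recovers synthetic organelle ground truth", {
  scn <- generateOrganelleScene(sceneSpec(seed = 7))
  msk <- makeOrganelleMask(scn$marker, scaleProfile("mitochondria"), airyDisc())
  expect_gte(maskIoU(maskRaster(msk), scn$truth@organelleMask), 0.5)

  scnER <- generateOrganelleScene(sceneSpec(organelleClass = "ER", seed = 11))
  mskER <- makeOrganelleMask(scnER$marker, scaleProfile("ER"), airyDisc())
  # the reticular web is harder: the 0.5-SD threshold sits near the ridge
  # response, so coverage is partial but well above chance
  expect_gte(maskRecall(maskRaster(mskER), scnER$truth@organelleMask), 0.45)
  expect_gte(maskIoU(maskRaster(mskER), scnER$truth@organelleMask), 0.45)

  const <- matrix(5, 32, 32)
  expect_false(any(maskRaster(makeOrganelleMask(const, scaleProfile("ER"), airyDisc()))))
})
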