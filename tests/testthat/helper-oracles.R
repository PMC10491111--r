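# Independent brute-force oracles.  These share no code with the package:
# dense 2-D convolution with per-pixel neighborhood extraction, a modular
# formula for symmetric reflection, and explicit per-pixel loops for the
# wavelet product, threshold and dilation.

# Symmetric (half-sample) reflection via modular arithmetic:
# the reflected sequence has period 2n: 1..n, n..1, 1..n, ...
oracleReflect <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  j[j < 0L] <- j[j < 0L] + 2L * n
  ifelse(j < n, j + 1L, 2L * n - j)
}

oracleKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Dense (non-separable) Gaussian convolution: for every pixel, extract the
# reflected neighborhood and sum against the full 2-D kernel.
oracleGaussianBlur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  k1 <- oracleKernel1d(sigma)
  K2 <- outer(k1, k1)
  r <- (length(k1) - 1L) %/% 2L
  ny <- nrow(image); nx <- ncol(image)
  out <- matrix(0, ny, nx)
  for (y in seq_len(ny)) {
    ys <- oracleReflect(seq(y - r, y + r), ny)
    for (x in seq_len(nx)) {
      xs <- oracleReflect(seq(x - r, x + r), nx)
      out[y, x] <- sum(K2 * image[ys, xs])
    }
  }
  out
}

# Full wavelet-product mask pipeline, recomputed pixel by pixel.
oracleMask <- function(image, scaleMultiples, airyRadiusPx,
                       thresholdSdFactor = 0.5, dilationPx = 0L,
                       normalization = "geometric_mean") {
  filtered <- lapply(scaleMultiples, function(m)
    oracleGaussianBlur(image, m * airyRadiusPx))
  n <- length(filtered)
  wavelets <- lapply(seq_len(n - 1L), function(i)
    filtered[[i]] - filtered[[i + 1L]])
  prod <- matrix(1, nrow(image), ncol(image))
  for (w in wavelets) prod <- prod * pmax(w, 0)
  if (normalization == "geometric_mean")
    prod <- prod^(1 / length(wavelets))
  mu <- mean(image)
  thr <- thresholdSdFactor * sqrt(sum((image - mu)^2) / length(image))
  mask <- prod > thr
  if (dilationPx > 0L) {
    ny <- nrow(mask); nx <- ncol(mask)
    out <- matrix(FALSE, ny, nx)
    for (y in seq_len(ny)) for (x in seq_len(nx)) {
      if (!mask[y, x]) next
      for (dy in -dilationPx:dilationPx) for (dx in -dilationPx:dilationPx) {
        if (dy * dy + dx * dx > dilationPx^2) next
        yy <- y + dy; xx <- x + dx
        if (yy >= 1L && yy <= ny && xx >= 1L && xx <= nx) out[yy, xx] <- TRUE
      }
    }
    mask <- out
  }
  mask
}

# Small random test image with smooth structure plus noise.
randomTestImage <- function(n, seed) {
  set.seed(seed)
  base <- matrix(0, n, n)
  for (i in 1:3) {
    cy <- runif(1, 1, n); cx <- runif(1, 1, n)
    Y <- matrix(seq_len(n), n, n); X <- t(Y)
    base <- base + runif(1, 50, 150) * exp(-((Y - cy)^2 + (X - cx)^2) / runif(1, 2, 8))
  }
  base + matrix(rnorm(n * n, 100, 5), n, n)
}

maskIoU <- function(a, b) sum(a & b) / sum(a | b)
maskRecall <- function(mask, truth) sum(mask & truth) / sum(truth)
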