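# Internal numerics shared across modules.

# Run `expr` under a fixed RNG state, restoring the caller's state after.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Normalized 1-D Gaussian kernel sampled on the integer grid, truncated at
# ceiling(4 sigma).  sigma = 0 degenerates to the identity kernel.
gaussianKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Map out-of-range 1-based indices onto 1..n by symmetric (half-sample)
# reflection: ... 2 1 | 1 2 ... n | n n-1 ...
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  # fold repeatedly for kernels wider than the image
  repeat {
    below <- i < 1L
    above <- i > n
    if (!any(below) && !any(above)) break
    i[below] <- 1L - i[below]
    i[above] <- 2L * n + 1L - i[above]
  }
  i
}

# n x n matrix applying 1-D convolution with `kernel` under symmetric
# reflection; filtered = M %*% x.
convolutionMatrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  idx <- seq_len(n)
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    src <- reflectIndex(idx + off, n)
    M[cbind(idx, src)] <- M[cbind(idx, src)] + kernel[j]
  }
  M
}

# Separable Gaussian blur with symmetric-reflection boundaries.
gaussianBlur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  if (any(!is.finite(image))) {
    bad <- which(!is.finite(image), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite pixel at (y=%d, x=%d)", bad[1], bad[2]))
  }
  k <- gaussianKernel1d(sigma)
  My <- convolutionMatrix(nrow(image), k)
  Mx <- convolutionMatrix(ncol(image), k)
  My %*% image %*% t(Mx)
}

# Population (denominator n) standard deviation.
sdPop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Integer offsets (dy, dx) of the Euclidean disk dy^2 + dx^2 <= r^2.
diskOffsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

stopIfNotFinite <- function(image, what = "image") {
  if (any(!is.finite(image))) {
    bad <- which(!is.finite(image), arr.ind = TRUE)[1, ]
    stop(sprintf("%s has non-finite pixel at (y=%d, x=%d)", what, bad[1], bad[2]))
  }
  invisible(TRUE)
}
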