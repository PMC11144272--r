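# Internal image helpers. Images are numeric matrices, rows = y, cols = x,
# intensities in [0, 1] unless stated otherwise.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

clamp01 <- function(x) clamp(x, 0, 1)

# run expr with a local RNG seeded from `seed`, restoring the caller's state
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

gaussianKernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur with replicate borders
gaussianBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussianKernel1d(sigma)
  sepConvolve(img, k, k)
}

# separable correlation with replicate borders; ky along rows, kx along cols
sepConvolve <- function(img, ky, kx) {
  img <- convolve1d(img, ky, along = 1L)
  convolve1d(img, kx, along = 2L)
}

convolve1d <- function(img, k, along = 1L) {
  r <- (length(k) - 1L) %/% 2L
  n <- dim(img)[along]
  idx <- function(i) clamp(i, 1L, n)
  out <- array(0, dim(img))
  for (o in seq_along(k)) {
    off <- o - r - 1L
    sel <- idx(seq_len(n) + off)
    out <- out + k[o] * (if (along == 1L) img[sel, , drop = FALSE]
                         else img[, sel, drop = FALSE])
  }
  out
}

# reflect an index vector into [1, n] (border reflection without repeat)
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  i <- (i - 1L) %% p
  i <- ifelse(i < 0, i + p, i)
  as.integer(ifelse(i >= n, p - i, i)) + 1L
}

# bilinear sampling at fractional coordinates (Y, X), reflect border;
# Y, X are matrices (or vectors) of 1-based row/col positions
bilinearSample <- function(img, Y, X) {
  h <- nrow(img); w <- ncol(img)
  y0 <- floor(Y); x0 <- floor(X)
  fy <- Y - y0; fx <- X - x0
  iy0 <- reflectIndex(as.integer(y0), h)
  iy1 <- reflectIndex(as.integer(y0) + 1L, h)
  ix0 <- reflectIndex(as.integer(x0), w)
  ix1 <- reflectIndex(as.integer(x0) + 1L, w)
  v00 <- img[cbind(c(iy0), c(ix0))]
  v01 <- img[cbind(c(iy0), c(ix1))]
  v10 <- img[cbind(c(iy1), c(ix0))]
  v11 <- img[cbind(c(iy1), c(ix1))]
  out <- (1 - c(fy)) * ((1 - c(fx)) * v00 + c(fx) * v01) +
    c(fy) * ((1 - c(fx)) * v10 + c(fx) * v11)
  if (is.matrix(Y)) matrix(out, nrow(Y), ncol(Y)) else out
}

# bicubic (Keys) sampling at fractional coordinates, clamped border
cubicSample <- function(img, Y, X) {
  h <- nrow(img); w <- ncol(img)
  y0 <- floor(Y); x0 <- floor(X)
  fy <- c(Y - y0); fx <- c(X - x0)
  y0 <- as.integer(y0); x0 <- as.integer(x0)
  out <- numeric(length(fy))
  wsum <- numeric(length(fy))
  for (m in -1:2) {
    wy <- keysKernel(fy - m)
    iy <- clamp(c(y0) + m, 1L, h)
    for (nn in -1:2) {
      wx <- keysKernel(fx - nn)
      ix <- clamp(c(x0) + nn, 1L, w)
      wgt <- wy * wx
      out <- out + wgt * img[cbind(iy, ix)]
      wsum <- wsum + wgt
    }
  }
  out <- out / wsum
  if (is.matrix(Y)) matrix(out, nrow(Y), ncol(Y)) else out
}

# warp an image by a homography H mapping target (x, y, 1) -> source;
# output pixel (r, c) is sampled at the H-image of (c, r). An optional
# displacement field is composed in (field first), so drift application
# and its inverse need only a single resampling pass.
warpHomography <- function(img, H, flow = NULL) {
  h <- nrow(img); w <- ncol(img)
  cc <- matrix(rep(seq_len(w), each = h), h, w)
  rr <- matrix(rep(seq_len(h), times = w), h, w)
  if (!is.null(flow)) {
    rr <- rr + flow[, , 1]
    cc <- cc + flow[, , 2]
  }
  d <- H[3, 1] * cc + H[3, 2] * rr + H[3, 3]
  Xs <- (H[1, 1] * cc + H[1, 2] * rr + H[1, 3]) / d
  Ys <- (H[2, 1] * cc + H[2, 2] * rr + H[2, 3]) / d
  cubicSample(img, Ys, Xs)
}

# warp through a displacement field: output(r, c) = img(r + dy, c + dx)
warpFlow <- function(img, flow) {
  h <- nrow(img); w <- ncol(img)
  cc <- matrix(rep(seq_len(w), each = h), h, w)
  rr <- matrix(rep(seq_len(h), times = w), h, w)
  cubicSample(img, rr + flow[, , 1], cc + flow[, , 2])
}

# Keys cubic convolution kernel (a = -0.5), the classic bicubic kernel
keysKernel <- function(s) {
  s <- abs(s)
  ifelse(s <= 1, 1.5 * s^3 - 2.5 * s^2 + 1,
         ifelse(s < 2, -0.5 * s^3 + 2.5 * s^2 - 4 * s + 2, 0))
}

# separable bicubic resampling to (newH, newW); constant images preserved
resizeBicubic <- function(img, newH, newW) {
  img <- cubicResampleAxis(img, newH, along = 1L)
  cubicResampleAxis(img, newW, along = 2L)
}

cubicResampleAxis <- function(img, newN, along = 1L) {
  n <- dim(img)[along]
  if (newN == n) return(img)
  # align centers: target i maps to source position
  pos <- (seq_len(newN) - 0.5) * n / newN + 0.5
  i0 <- floor(pos)
  fr <- pos - i0
  outDim <- dim(img); outDim[along] <- newN
  out <- array(0, outDim)
  wsum <- numeric(newN)
  for (m in -1:2) {
    wgt <- keysKernel(fr - m)
    sel <- clamp(as.integer(i0) + m, 1L, n)
    contrib <- if (along == 1L) img[sel, , drop = FALSE] else img[, sel, drop = FALSE]
    out <- out + contrib * (if (along == 1L) wgt else rep(wgt, each = dim(img)[1]))
    wsum <- wsum + wgt
  }
  # kernel weights sum to 1 analytically; normalize to guard rounding
  out / (if (along == 1L) wsum else rep(wsum, each = dim(img)[1]))
}

# linear-interpolation percentile between closest order statistics (type 7)
linearPercentile <- function(x, q) {
  unname(stats::quantile(x, q / 100, type = 7, names = FALSE))
}

# min-max normalization; flat inputs map to all-zero rather than 0/0
minMaxNormalize <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] < .Machine$double.eps) return(array(0, dim(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

toModelRange <- function(x) 2 * x - 1

fromModelRange <- function(x) (x + 1) / 2

normalizedCrossCorrelation <- function(a, b) {
  a <- c(a) - mean(a); b <- c(b) - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
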