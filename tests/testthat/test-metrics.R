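test_that("FSIM is reflexive, bounded, symmetric and noise-monotone", {
  a <- toyPhantom(3, 128)
  expect_equal(fsim(a, a), 1, tolerance = 1e-6)
  worse <- 0
  for (seed in 1:5) {
    weak <- applyNoise(a, NoiseModel(dwell = 16, seed = seed))
    strong <- applyNoise(a, NoiseModel(dwell = 1, seed = seed + 50))
    if (fsim(a, strong) < fsim(a, weak)) worse <- worse + 1
  }
  expect_gte(worse, 4)
  set.seed(2)
  for (i in 1:10) {
    x <- matrix(stats::runif(64 * 64), 64, 64)
    y <- matrix(stats::runif(64 * 64), 64, 64)
    s <- fsim(x, y)
    expect_gte(s, 0); expect_lte(s, 1)
  }
  b <- applyNoise(a, NoiseModel(dwell = 4, seed = 1))
  expect_equal(fsim(a, b), fsim(b, a), tolerance = 1e-6)
  expect_error(fsim(a, a[1:64, ]), "dimensions")
})

test_that("FRC is one on identical inputs and null on independent noise", {
  a <- toyPhantom(4, 96)
  self <- frc(a, a)
  expect_true(all(abs(self$correlation[self$freq > 0] - 1) < 1e-8))
  set.seed(5)
  n1 <- matrix(stats::rnorm(128^2), 128, 128)
  n2 <- matrix(stats::rnorm(128^2), 128, 128)
  null <- frc(n1, n2)
  ringCorr <- null$correlation[null$freq > 0]
  se <- stats::sd(ringCorr) / sqrt(length(ringCorr))
  expect_lt(abs(mean(ringCorr)), 3 * se + 0.01)
  expect_error(frc(a, matrix(0, 96, 64)), "square")
})

test_that("FRC cutoff tracks a constructed band limit", {
  # band-limited image: no energy above k0
  set.seed(6)
  n <- 128; k0 <- 0.15
  g <- emrestore:::fftFreqGrid(n, n)
  spec <- matrix(stats::rnorm(n^2) + 1i * stats::rnorm(n^2), n, n)
  spec[g$r > k0] <- 0
  img <- Re(stats::fft(spec, inverse = TRUE)) / n^2
  img <- (img - min(img)) / diff(range(img))
  noisy <- img + matrix(stats::rnorm(n^2, 0, 1e-3), n, n)
  cur <- frc(img, noisy)
  expect_lte(cur$cutoff, k0 + 1 / n + 1e-9)
  expect_gt(cur$cutoff, k0 - 0.03)
})

test_that("resolution estimation localizes known content and units scale", {
  cc <- matrix(rep(1:128, each = 128), 128, 128)
  set.seed(1)
  k <- 24 / 128
  sine <- 0.5 + 0.4 * sin(2 * pi * k * cc) +
    matrix(stats::rnorm(128^2, 0, 0.02), 128, 128)
  est <- resolutionEstimate(sine)
  ringW <- diff(est$radii)[1]
  expect_lt(abs(est$cutoff - k), 2 * ringW)
  a <- toyPhantom(5, 128)
  rSharp <- resolutionEstimate(a)$resolution
  rBlur <- resolutionEstimate(emrestore:::gaussianBlur(a, 1.5))$resolution
  expect_gt(rBlur, rSharp)
  expect_equal(resolutionEstimate(a, pixelSize = 2)$resolution,
               resolutionEstimate(a, pixelSize = 4)$resolution / 2)
  expect_error(resolutionEstimate(matrix(0.5, 64, 64)), "constant")
})

test_that("resolution ratio orders sharp and blurred predictions", {
  a <- toyPhantom(6, 128)
  blur <- emrestore:::gaussianBlur(a, 1.5)
  expect_equal(resolutionRatio(a, a), 1, tolerance = 1e-9)
  expect_lt(resolutionRatio(a, blur), 1)
  expect_gt(resolutionRatio(blur, a), 1)
})

test_that("IoU counts overlaps and honours the empty-mask convention", {
  m <- matrix(0, 20, 20)
  sq1 <- m; sq1[1:10, 1:10] <- 1
  sq2 <- m; sq2[6:15, 1:10] <- 1
  expect_equal(iou(sq1, sq2), 50 / 150)
  expect_equal(iou(sq1, sq1), 1)
  disj <- m; disj[15:20, 15:20] <- 1
  expect_equal(iou(sq1, disj), 0)
  expect_equal(iou(m, m), 1)
  # opening removes a speck that would otherwise poison the union
  speck <- m; speck[3, 15] <- 1
  expect_lt(iou(sq1, sq1 + speck), 1)
  expect_equal(iou(sq1, sq1 + speck, postprocess = "open"), 1)
  expect_error(iou(sq1, matrix(0, 10, 10)), "dimensions")
})

test_that("power spectra behave for noise, constants and real inputs", {
  set.seed(7)
  wn <- matrix(stats::rnorm(128^2), 128, 128)
  ps <- powerSpectrum(wn)
  pow <- expm1(ps)
  g <- emrestore:::fftFreqGrid(128, 128)
  rs <- emrestore:::fftshift2(g$r)
  ringMeans <- vapply(seq(0.05, 0.45, by = 0.1), function(r0)
    mean(pow[rs >= r0 & rs < r0 + 0.1]), numeric(1))
  expect_lt(max(ringMeans) / min(ringMeans), 1.1)
  cst <- powerSpectrum(matrix(0.3, 64, 64))
  expect_equal(which(cst == max(cst), arr.ind = TRUE)[1, ],
               c(row = 33, col = 33))
  expect_lt(max(cst[-33, -33]), 1e-12)
  # conjugate symmetry of a real input: point reflection through DC
  a <- toyPhantom(8, 64)
  psa <- powerSpectrum(a)
  sub <- psa[2:64, 2:64]
  expect_lt(max(abs(sub - sub[63:1, 63:1])), 1e-6)
})
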