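refCorners <- function(img, margin = 10) {
  n <- nrow(img); m <- ncol(img)
  cbind(c(margin, margin, m - margin, m - margin),
        c(margin, n - margin, margin, n - margin))
}

test_that("coarse alignment of an image onto itself is the identity", {
  img <- toyPhantom(5, 160)
  res <- coarseAlign(img, img)
  pts <- refCorners(img)
  proj <- emrestore:::applyHomographyPts(res@homography, pts)
  expect_lt(max(sqrt(rowSums((proj - pts)^2))), 0.5)
  expect_gte(res@nMatches, 4)
})

test_that("coarse alignment recovers a planted translation to subpixel", {
  img <- toyPhantom(6, 192)
  H <- rbind(c(1, 0, 7), c(0, 1, -4), c(0, 0, 1))
  drifted <- applyDrift(img, DriftModel(homography = H))$image
  res <- coarseAlign(drifted, img)
  pts <- refCorners(img, 16)
  err <- emrestore:::applyHomographyPts(res@homography, pts) -
    emrestore:::applyHomographyPts(H, pts)
  expect_lt(max(sqrt(rowSums(err^2))), 0.5)
})

test_that("structureless inputs raise a registration failure", {
  set.seed(1)
  noise <- matrix(stats::runif(160 * 160), 160, 160)
  img <- toyPhantom(7, 160)
  err <- tryCatch(coarseAlign(noise, img),
                  registrationFailure = function(e) e)
  expect_s3_class(err, "registrationFailure")
  expect_true(is.numeric(err$nMatches))
})

test_that("fine alignment of identical inputs finds essentially no flow", {
  img <- toyPhantom(8, 128)
  res <- fineAlign(img, img)
  expect_lt(res@residual, 0.2)
})

test_that("fine alignment recovers a constant subpatch shift", {
  img <- toyPhantom(9, 160)
  shifted <- emrestore:::warpFlow(img, array(2, c(160, 160, 2)))
  res <- fineAlign(shifted, img)
  # shifted(r, c) = img(r + 2, c + 2), so the correcting flow is -2
  expect_lt(abs(stats::median(res@flowField[, , 1]) + 2), 0.5)
  expect_lt(abs(stats::median(res@flowField[, , 2]) + 2), 0.5)
})

test_that("fine alignment halves sinusoidal misalignment", {
  img <- toyPhantom(10, 160)
  cc <- matrix(rep(1:160, each = 160), 160, 160)
  fld <- array(0, c(160, 160, 2))
  fld[, , 1] <- 1.5 * sin(2 * pi * cc / 64)
  fld[, , 2] <- 1.5 * cos(2 * pi * t(cc) / 64)
  moved <- emrestore:::warpFlow(img, fld)
  res <- fineAlign(moved, img)
  cen <- 30:130
  ncc <- emrestore:::normalizedCrossCorrelation
  before <- 1 - ncc(moved[cen, cen], img[cen, cen])
  after <- 1 - ncc(res@warped[cen, cen], img[cen, cen])
  expect_lt(after, before / 2)
  expect_error(fineAlign(img[1:100, ], img), "mismatch")
})

test_that("patch tiling follows the stride with edge snapping", {
  img452 <- matrix(0, 452, 452)
  g <- cropPatches(img452, 256, 196)$grid
  expect_equal(nPatches(g), 4)
  expect_equal(sort(unique(patchOrigins(g)[, 1])), c(0, 196))
  gExact <- cropPatches(matrix(0, 256, 256), 256, 196)$grid
  expect_equal(nPatches(gExact), 1)
  expect_equal(patchOrigins(gExact)[1, ], c(0, 0))
  g500 <- cropPatches(matrix(0, 500, 256), 256, 196)$grid
  expect_equal(sort(unique(patchOrigins(g500)[, 1])), c(0, 196, 244))
  expect_equal(nPatches(g500), 3)
  expect_error(cropPatches(matrix(0, 100, 300), 256, 196), "smaller")
})

test_that("patch counts match brute-force enumeration", {
  bruteCount <- function(n, ps, st) {
    starts <- 0L
    while (starts[length(starts)] + st + ps <= n)
      starts <- c(starts, starts[length(starts)] + st)
    if (starts[length(starts)] != n - ps) starts <- c(starts, n - ps)
    length(unique(starts))
  }
  set.seed(42)
  for (i in 1:50) {
    ps <- sample(8:64, 1)
    st <- sample(4:ps, 1)
    h <- ps + sample(0:200, 1); w <- ps + sample(0:200, 1)
    g <- cropPatches(matrix(0, h, w), ps, st)$grid
    expect_equal(nPatches(g), bruteCount(h, ps, st) * bruteCount(w, ps, st))
    expect_true(all(patchOrigins(g) >= 0))
  }
})

test_that("training-pair construction aligns, tiles and skips bad pairs", {
  img <- toyPhantom(11, 452)
  H <- rbind(c(1, 0, 3), c(0, 1, 2), c(0, 0, 1))
  drifted <- applyDrift(img, DriftModel(homography = H,
                                        smoothFieldAmplitude = 1,
                                        smoothFieldScale = 64, seed = 2))
  noisy <- applyNoise(drifted$image, NoiseModel(dwell = 8, seed = 3))
  set.seed(4)
  junk <- matrix(stats::runif(452^2), 452, 452)
  out <- buildTrainingPairs(list(noisy, junk), list(img, img),
                            patchSize = 256, stride = 196)
  expect_equal(out$skipped, 2L)
  expect_length(out$pairs, 4)
  expect_equal(dim(out$pairs[[1]]$raw), c(256, 256))
})

test_that("undrifted pairs pass through without resampling", {
  img <- toyPhantom(12, 300)
  out <- buildTrainingPairs(list(img), list(img), patchSize = 256,
                            stride = 196)
  expect_length(out$pairs, 4)
  crops <- cropPatches(img, 256, 196)$patches
  for (k in seq_along(crops))
    expect_lt(max(abs(out$pairs[[k]]$raw - crops[[k]])), 1e-6)
})

test_that("drift is recovered end to end with high fidelity", {
  ncc <- emrestore:::normalizedCrossCorrelation
  okCount <- 0
  for (seed in 1:5) {
    set.seed(1000 + seed)
    img <- toyPhantom(20 + seed, 192)
    H <- rbind(c(1, 0, stats::runif(1, -6, 6)),
               c(0, 1, stats::runif(1, -6, 6)), c(0, 0, 1))
    dr <- applyDrift(img, DriftModel(homography = H,
                                     smoothFieldAmplitude = 1.5,
                                     smoothFieldScale = 48,
                                     seed = seed))
    noisy <- applyNoise(dr$image, NoiseModel(dwell = 4, seed = seed))
    # estimate the transforms from the noisy pair, then apply them to the
    # clean drifted scene so that acquisition noise does not cap the score
    ok <- tryCatch({
      ca <- coarseAlign(noisy, img)
      fa <- fineAlign(ca@warped, img)
      alignedClean <- emrestore:::warpHomography(
        dr$image, solve(ca@homography), flow = fa@flowField)
      cen <- 25:168
      ncc(alignedClean[cen, cen], img[cen, cen]) >= 0.98
    }, registrationFailure = function(e) FALSE)
    if (ok) okCount <- okCount + 1
  }
  expect_gte(okCount, 3)
})
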