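test_that("SR input rescaling doubles the patch and preserves content", {
  up <- prepareSRInput(matrix(0.37, 128, 128), 2)
  expect_equal(dim(up), c(256, 256))
  expect_lt(max(abs(up - 0.37)), 1e-6)
  # band-limited sinusoid survives a downsample/rescale round trip
  cc <- matrix(rep(1:128, each = 128), 128, 128)
  sig <- 0.5 + 0.3 * sin(2 * pi * cc / 32) * cos(2 * pi * t(cc) / 24)
  low <- emrestore:::meanPool(sig, 2)
  rec <- prepareSRInput(low, 2)
  expect_gt(stats::cor(c(rec), c(sig)), 0.99)
  expect_error(prepareSRInput(matrix(0, 4, 4), -1), "positive")
  expect_error(prepareSRInput(matrix(0, 4, 8)), "square")
})

test_that("ensemble mean and SD follow the K-sample formulas", {
  sch <- toySchedule(10)
  a <- 2 * toyPhantom(2, 32) - 1
  d <- matrix(0.3, 32, 32); d[1:16, ] <- -0.2
  net <- sequenceOracle(sch, list(a, a + d))
  ens <- predictEnsemble(a * 0, net, sch, K = 2, seeds = c(1, 2))
  expect_equal(ensembleMean(ens), a + d / 2, tolerance = 1e-6)
  expect_equal(ensembleStd(ens), abs(d) / sqrt(2), tolerance = 1e-6)
  # identical samples: zero SD
  net1 <- teacherOracle(a, sch)
  ensSame <- predictEnsemble(a * 0, net1, sch, K = 3, seeds = 1:3)
  expect_lt(max(ensembleStd(ensSame)), 1e-6)
  expect_error(predictEnsemble(a * 0, net1, sch, K = 0, seeds = integer(0)),
               "K must be")
  ens1 <- predictEnsemble(a * 0, net1, sch, K = 1, seeds = 7)
  expect_true(all(ensembleStd(ens1) == 0))
})

test_that("ensemble statistics agree with a brute-force oracle", {
  set.seed(8)
  for (K in c(2, 3, 5)) {
    stack <- array(stats::rnorm(16 * 16 * K), c(16, 16, K))
    fast <- emrestore:::ensembleStdFast(stack)
    slow <- apply(stack, c(1, 2), stats::sd)
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("stitching is exact on mosaics and convex in overlaps", {
  img <- matrix(stats::runif(300 * 300), 300, 300)
  # non-overlapping grid: stride == patch size
  cp <- cropPatches(img, 100, 100)
  expect_equal(stitchPatches(cp$patches, cp$grid), img)
  # overlapping grid reproduces the source (patches are crops of it)
  cp2 <- cropPatches(img, 128, 96)
  expect_lt(max(abs(stitchPatches(cp2$patches, cp2$grid) - img)), 1e-12)
  # constant patches: overlap stays exactly the constant
  flat <- lapply(cp2$patches, function(p) matrix(0.61, 128, 128))
  expect_lt(max(abs(stitchPatches(flat, cp2$grid) - 0.61)), 1e-9)
  # normalized weights sum to one everywhere: all-ones patches map to one
  ones <- lapply(cp2$patches, function(p) matrix(1, 128, 128))
  expect_lt(max(abs(stitchPatches(ones, cp2$grid) - 1)), 1e-6)
  expect_error(stitchPatches(cp2$patches[-1], cp2$grid), "patches")
})

test_that("stitched output is independent of patch processing order", {
  img <- matrix(stats::runif(250 * 250), 250, 250)
  cp <- cropPatches(img, 128, 96)
  base <- stitchPatches(cp$patches, cp$grid)
  # process patches in reverse order, then place them back in grid order
  rev_processed <- rev(lapply(rev(cp$patches), function(p) p * 1))
  expect_identical(stitchPatches(rev_processed, cp$grid), base)
})

test_that("the default ensemble size is 2", {
  expect_equal(formals(predictEnsemble)$K, 2L)
  expect_equal(formals(restoreImage)$K, 2L)
  expect_equal(chooseK(toyPhantom(1, 64)), 2L)
  expect_error(chooseK(toyPhantom(1, 64), breaks = 1, values = c(3L, 2L)),
               "monotone")
})

test_that("full-image restoration with an identity oracle is plumbing-exact", {
  sch <- toySchedule(10)
  img <- toyPhantom(4, 96)
  net <- identityOracle(sch)
  out <- restoreImage(img, net, sch, mode = "denoise", K = 2,
                      patchSize = 64, stride = 48, seed = 3)
  expect_lt(max(abs(out$image - img)), 1e-4)
  expect_true(isReliable(out$report))
  out2 <- restoreImage(img, net, sch, mode = "denoise", K = 2,
                       patchSize = 64, stride = 48, seed = 3)
  expect_identical(out$image, out2$image)
})
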