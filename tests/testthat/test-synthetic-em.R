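test_that("phantom generation is deterministic and seed-sensitive", {
  spec <- PhantomSpec(height = 96, width = 96, seed = 1)
  expect_identical(generatePhantom2D(spec), generatePhantom2D(spec))
  other <- generatePhantom2D(PhantomSpec(height = 96, width = 96, seed = 2))
  expect_gt(mean(abs(generatePhantom2D(spec) - other)), 0.01)
  img <- generatePhantom2D(spec)
  expect_true(all(img >= 0 & img <= 1))
})

test_that("organelle-free phantom with infinite texture scale is flat", {
  img <- generatePhantom2D(PhantomSpec(height = 64, width = 64,
                                       nOrganelles = 0,
                                       textureScale = Inf, seed = 1))
  expect_lt(stats::var(c(img)), 1e-3)
})

test_that("undersized phantoms are rejected", {
  expect_error(generatePhantom2D(PhantomSpec(height = 32, width = 96)),
               "64")
  expect_error(generatePhantomVolume(PhantomSpec(depth = 8)), "16")
})

test_that("acquisition noise vanishes in the long-dwell limit and is seeded", {
  clean <- toyPhantom(3, 96)
  nearClean <- applyNoise(clean, NoiseModel(dwell = 1e9, seed = 1))
  expect_lt(max(abs(nearClean - clean)), 1e-3)
  m <- NoiseModel(dwell = 2, seed = 7)
  expect_identical(applyNoise(clean, m), applyNoise(clean, m))
  expect_error(applyNoise(clean, NoiseModel(dwell = 0)), "dwell")
})

test_that("noise SD follows the dwell^(-1/2) law on flat images", {
  flat <- matrix(0.5, 1000, 1000)
  sds <- vapply(c(1, 4, 16), function(d)
    stats::sd(applyNoise(flat, NoiseModel(dwell = d, seed = d + 10))),
    numeric(1))
  expect_lt(abs(sds[1] / sds[2] - 2), 0.3)   # ratio 2 +- 15%
  expect_lt(abs(sds[2] / sds[3] - 2), 0.3)
  # direct law check against dwell^(-1/2)
  expect_lt(abs(sds[1] / sds[3] - 4), 0.6)
})

test_that("drift with identity homography and zero amplitude is a no-op", {
  img <- toyPhantom(2, 96)
  out <- applyDrift(img, DriftModel())
  expect_equal(out$image, img)
  expect_true(all(out$flowField == 0))
})

test_that("pure translation drift lands at the planted shift", {
  img <- toyPhantom(4, 128)
  H <- rbind(c(1, 0, 5), c(0, 1, -3), c(0, 0, 1))
  out <- applyDrift(img, DriftModel(homography = H))
  # drifted(r, c) = img(r - 3, c + 5): phase correlation must recover it
  pk <- phaseCorrPeak(out$image[20:109, 20:109], img[20:109, 20:109])
  expect_equal(unname(pk), c(-3, 5))
})

test_that("smooth drift field respects its amplitude bound", {
  img <- toyPhantom(5, 96)
  out <- applyDrift(img, DriftModel(smoothFieldAmplitude = 2,
                                    smoothFieldScale = 64, seed = 3))
  mag <- sqrt(out$flowField[, , 1]^2 + out$flowField[, , 2]^2)
  expect_lte(max(mag), 2 + 1e-12)
  expect_gt(max(mag), 1.9)  # normalization reaches the bound
})

test_that("degenerate drift models are rejected", {
  expect_error(DriftModel(homography = matrix(0, 3, 3)), "invertible")
  expect_error(DriftModel(smoothFieldAmplitude = -1), ">= 0")
})

test_that("phantom volumes are deterministic, isotropic and z-continuous", {
  spec <- PhantomSpec(height = 48, width = 48, depth = 24, seed = 6)
  v1 <- generatePhantomVolume(spec)
  expect_identical(volumeData(v1), volumeData(generatePhantomVolume(spec)))
  expect_true(all(voxelSize(v1) == voxelSize(v1)[1]))
  d <- volumeData(v1)
  lag <- function(k) mean(vapply(seq_len(dim(d)[1] - k), function(z)
    stats::cor(c(d[z, , ]), c(d[z + k, , ])), numeric(1)))
  expect_gt(lag(1), lag(8))
})

test_that("paired acquisitions default to an 18x reference dwell ratio", {
  expect_equal(formals(simulateDenoisePairs)$referenceDwellRatio, 18)
  pairs <- simulateDenoisePairs(2, side = 64, dwell = 1, seed = 3)
  # the reference scan must be much cleaner than the raw scan
  for (p in pairs) {
    expect_lt(mean((p$reference - p$clean)^2),
              mean((p$raw - p$clean)^2) / 4)
  }
})
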