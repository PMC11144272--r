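test_that("axial downsampling keeps mod-f layers and scales the voxel", {
  vol <- EMVolume(array(stats::runif(1024 * 2 * 2), c(1024, 2, 2)),
                  voxelSize = c(8, 8, 8))
  an <- downsampleAxial(vol, 6)
  expect_equal(voxelSize(an), c(48, 8, 8))
  expect_equal(nLayers(an), 171)      # layers 1, 7, ..., 1021
  expect_equal(volumeData(an)[2, , ], volumeData(vol)[7, , ])
  expect_identical(downsampleAxial(vol, 1), vol)
  expect_error(downsampleAxial(vol, 0), ">= 1")
  expect_equal(interpolationCount(an), 5L)
})

test_that("retained-layer counts match brute-force enumeration", {
  set.seed(3)
  for (i in 1:100) {
    M <- sample(4:200, 1)
    f <- sample(seq_len(max(1, M %/% 2)), 1)  # keep >= 2 layers
    vol <- EMVolume(array(0, c(M, 2, 2)))
    brute <- if (f == 1) M else sum(seq_len(M) %% f == 1)
    expect_equal(nLayers(downsampleAxial(vol, f)), brute)
  }
})

test_that("z-axis training samples follow the u / u+R+1 index rule", {
  v <- array(stats::runif(13 * 8 * 8), c(13, 8, 8))
  vol <- EMVolume(v, voxelSize = c(8, 8, 8))
  samples <- buildTrainingSamplesI(vol, R = 5)
  expect_length(samples, 13 - 5 - 1)    # valid u = 1..7
  s1 <- samples[[1]]
  toM <- emrestore:::toModelRange
  expect_equal(s1$cond[, , 1], toM(v[1, , ]))
  expect_equal(s1$cond[, , 2], toM(v[7, , ]))   # lower = c^(u+R+1)
  expect_length(s1$targets, 5)
  for (j in 1:5) expect_equal(s1$targets[[j]], toM(v[1 + j, , ]))
  expect_error(buildTrainingSamplesI(vol, R = 0), "empty")
  # boundary: M = R + 2 leaves exactly one anchor
  volMin <- EMVolume(array(0, c(7, 4, 4)))
  expect_length(buildTrainingSamplesI(volMin, R = 5), 1)
  expect_error(buildTrainingSamplesI(EMVolume(array(0, c(6, 4, 4))), R = 5),
               "at least")
})

test_that("y-axis training samples are XZ views with the same arithmetic", {
  v <- array(stats::runif(13 * 64 * 32), c(13, 64, 32))
  vol <- EMVolume(v, voxelSize = c(48, 8, 8))
  samples <- buildTrainingSamplesA(vol, R = 5)
  expect_length(samples, 64 - 5 - 1)
  expect_equal(dim(samples[[1]]$cond), c(13, 32, 2))  # (Z, X) slices
  expect_equal(samples[[1]]$cond[, , 1],
               emrestore:::toModelRange(v[, 1, ]))
  expect_equal(samples[[1]]$targets[[2]],
               emrestore:::toModelRange(v[, 3, ]))
  expect_error(buildTrainingSamplesA(EMVolume(array(0, c(5, 6, 5))), R = 5),
               "too small")
  # the anisotropic-only variant caps training at 1200 epochs
  expect_equal(vemATrainConfig()$maxEpochs, 1200L)
})

test_that("isotropic inference interleaves M + (M-1)R layers correctly", {
  sch <- toySchedule(10)
  v <- array(stats::runif(3 * 16 * 16), c(3, 16, 16))
  vol <- EMVolume(v, voxelSize = c(48, 8, 8))
  R <- 5
  oracle <- linearBlendOracle(sch, R)
  out <- inferIsotropic(vol, oracle, sch, R = R, K = 2, seed = 2)
  expect_equal(nLayers(out$volume), 3 + 2 * R)   # M + (M-1) R
  expect_equal(voxelSize(out$volume), c(8, 8, 8))
  vol2 <- EMVolume(v[1:2, , ], voxelSize = c(48, 8, 8))
  expect_equal(nLayers(inferIsotropic(vol2, oracle, sch, R = R,
                                      seed = 1)$volume), 7)
  # original layers preserved at output index u * (R+1), zero-based
  od <- volumeData(out$volume)
  for (u in 1:3) expect_equal(od[(u - 1) * (R + 1) + 1, , ], v[u, , ])
  # linear-blend oracle reproduces linear interpolation exactly
  for (u in 1:2) for (j in 1:R) {
    lin <- ((R + 1 - j) * v[u, , ] + j * v[u + 1, , ]) / (R + 1)
    expect_lt(max(abs(od[(u - 1) * (R + 1) + 1 + j, , ] - lin)), 1e-5)
  }
  # R = 0: identity
  out0 <- inferIsotropic(vol, oracle, sch, R = 0)
  expect_identical(volumeData(out0$volume), v)
  expect_error(inferIsotropic(EMVolume(array(0, c(2, 4, 4)))[FALSE], oracle,
                              sch), class = "error")
})

test_that("cubic baseline reproduces constants and degree-1 profiles", {
  d <- c(6, 8, 8)
  const <- EMVolume(array(0.4, d), voxelSize = c(48, 8, 8))
  out <- cubicBaseline(const, 6)
  expect_equal(nLayers(out), 6 + 5 * 5)
  expect_lt(max(abs(volumeData(out) - 0.4)), 1e-12)
  lin <- array(rep(seq(0.1, 0.6, length.out = 6), 64), d)
  outLin <- cubicBaseline(EMVolume(lin, voxelSize = c(48, 8, 8)), 6)
  fine <- seq(0.1, 0.6, length.out = 31)
  # interior gaps reproduce the linear profile exactly (edges replicate)
  expect_lt(max(abs(volumeData(outLin)[7:25, 1, 1] - fine[7:25])), 1e-6)
  expect_error(cubicBaseline(EMVolume(array(0, c(3, 4, 4))), 6), "at least")
})

test_that("cubic baseline matches a pointwise kernel-evaluation oracle", {
  set.seed(9)
  M <- 12
  prof <- 0.5 + 0.4 * sin(2 * pi * seq_len(M) / 16)
  v <- array(rep(prof, 16), c(M, 4, 4))
  vol <- EMVolume(v, voxelSize = c(32, 8, 8))
  out <- volumeData(cubicBaseline(vol, 4))
  keys <- function(s) {
    s <- abs(s)
    if (s <= 1) 1.5 * s^3 - 2.5 * s^2 + 1
    else if (s < 2) -0.5 * s^3 + 2.5 * s^2 - 4 * s + 2 else 0
  }
  for (probe in list(c(2, 1), c(5, 3), c(9, 2))) {
    u <- probe[1]; j <- probe[2]; fr <- j / 4
    idx <- u + (-1:2)
    w <- vapply(fr - (-1:2), keys, numeric(1))
    expected <- sum(w * prof[pmin(pmax(idx, 1), M)]) / sum(w)
    expect_equal(out[(u - 1) * 4 + 1 + j, 2, 2], expected,
                 tolerance = 1e-8)
  }
})
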