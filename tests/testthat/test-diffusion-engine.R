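test_that("noise schedules have the right constants and shape", {
  sch <- buildSchedule(Tsteps = 2, betaMin = 0.1, betaMax = 0.2)
  expect_equal(sch@alphaBar, c(0.9, 0.72))
  def <- buildSchedule()
  expect_equal(def@Tsteps, 1000L)
  expect_lt(def@alphaBar[1000], 0.01)
  expect_true(all(diff(def@alphaBar) < 0))
  cosine <- buildSchedule(100, kind = "cosine")
  expect_true(all(diff(cosine@alphaBar) < 0))
  expect_error(buildSchedule(100, betaMin = 0.5, betaMax = 0.2), "betaMin")
  expect_error(buildSchedule(1), "Tsteps")
})

test_that("forward noising matches its closed form and inverts", {
  sch <- toySchedule()
  x0 <- matrix(stats::rnorm(64), 8, 8)
  expect_equal(forwardNoise(x0, 7, x0 * 0, sch),
               sqrt(sch@alphaBar[7]) * x0)
  # scalar hand value: alphaBar = 0.64 -> 0.8 * 1 + 0.6 * 0.5 = 1.1
  schHand <- new("NoiseSchedule", Tsteps = 1L, beta = 0.36, alpha = 0.64,
                 alphaBar = 0.64, sigma2 = 0.36)
  expect_equal(forwardNoise(matrix(1), 1, matrix(0.5), schHand),
               matrix(1.1))
  set.seed(1)
  for (i in 1:10) {
    t <- sample.int(sch@Tsteps, 1)
    eps <- matrix(stats::rnorm(64), 8, 8)
    xt <- forwardNoise(x0, t, eps, sch)
    back <- (xt - sqrt(1 - sch@alphaBar[t]) * eps) / sqrt(sch@alphaBar[t])
    expect_lt(max(abs(back - x0)), 1e-6)
  }
  expect_error(forwardNoise(x0, 0, x0, sch), "outside")
  expect_error(forwardNoise(x0, 51, x0, sch), "outside")
})

test_that("difficulty loss evaluates, reduces to half-MSE, and is minimised at phi = |e|", {
  e <- matrix(stats::rnorm(100, sd = 2), 10, 10)
  zero <- e * 0
  expect_equal(difficultyLoss(e, zero, zero + 1), mean(e^2) / 2,
               tolerance = 1e-7)
  expect_equal(difficultyLoss(matrix(2), matrix(0), matrix(1)), 2)
  expect_equal(difficultyLoss(matrix(2), matrix(0), matrix(2)),
               0.5 + log(2), tolerance = 1e-7)
  # calculus oracle: dL/dphi = -e^2/phi^3 + 1/phi = 0 at phi* = |e|
  for (ev in c(0.5, 2, 3.7)) {
    phiStar <- stats::optimize(function(p)
      ev^2 / (2 * p^2) + log(p), c(1e-3, 50))$minimum
    expect_equal(phiStar, ev, tolerance = 1e-4)
  }
  expect_error(difficultyLoss(e, zero, zero), "positive")
})

test_that("reverse step matches the scalar hand value and inverts one-step diffusion", {
  schHand <- new("NoiseSchedule", Tsteps = 1L, beta = 0.1, alpha = 0.9,
                 alphaBar = 0.9, sigma2 = 0.1)
  oracle <- function(xt, t, cond, j) list(epsHat = matrix(0.5))
  out <- reverseStep(matrix(1), 1L, matrix(0), NULL, oracle, schHand)
  # (1/sqrt(0.9)) * (1 - (0.1 / sqrt(0.1)) * 0.5) = 0.88742...
  expect_equal(out$x[1, 1], 0.8874, tolerance = 1e-4)
  # T = 1: feeding back the exact forward eps recovers x0
  x0 <- matrix(stats::rnorm(64), 8, 8)
  eps <- matrix(stats::rnorm(64), 8, 8)
  xt <- forwardNoise(x0, 1, eps, schHand)
  rec <- reverseStep(xt, 1L, matrix(0, 8, 8), NULL,
                     function(...) list(epsHat = eps), schHand)
  expect_lt(max(abs(rec$x - x0)), 1e-5)
  badNet <- function(...) list(epsHat = matrix(0, 2, 2))
  expect_error(reverseStep(xt, 1L, matrix(0, 8, 8), NULL, badNet, schHand),
               "shape")
})

test_that("injected reverse noise has variance 1 - alpha_t", {
  sch <- toySchedule()
  t <- 30L
  zeroNet <- function(...) list(epsHat = matrix(0, 320, 320))
  xt <- matrix(0, 320, 320)
  set.seed(5)
  out <- reverseStep(xt, t, xt, NULL, zeroNet, sch)
  expect_equal(stats::var(c(out$x)), 1 - sch@alpha[t], tolerance = 0.03)
})

test_that("sampling is seed-deterministic and inverts a teacher trajectory", {
  sch <- toySchedule()
  x0 <- 2 * toyPhantom(3, 32) - 1
  oracle <- teacherOracle(x0, sch)
  s1 <- sampleRestoration(x0 * 0, oracle, sch, seed = 9)
  s2 <- sampleRestoration(x0 * 0, oracle, sch, seed = 9)
  expect_identical(s1$x0, s2$x0)
  expect_lt(mean((s1$x0 - x0)^2), 1e-8)
  expect_lt(max(abs(s1$x0 - x0)), 1e-4)
})

test_that("channel embedding is deterministic, discriminative and range-checked", {
  e1 <- channelEmbed(3, 5, 64)
  expect_identical(e1, channelEmbed(3, 5, 64))
  expect_length(e1, 64)
  for (j in 1:4) for (jp in (j + 1):5) {
    d <- sqrt(sum((channelEmbed(j, 5, 64) - channelEmbed(jp, 5, 64))^2))
    expect_gt(d, 0)
  }
  expect_error(channelEmbed(0, 5, 64), "j must lie")
  expect_error(channelEmbed(6, 5, 64), "j must lie")
  expect_error(channelEmbed(1, 5, 33), "even")
})

test_that("the network honours its output contract", {
  nf <- emrestore:::netForward
  net <- makeNetwork(condChannels = 1, baseWidth = 8, embDim = 16, seed = 2)
  out <- nf(net, matrix(0.1, 64, 64), matrix(0.2, 64, 64), t = 3)
  expect_equal(dim(out$epsHat), c(64, 64))
  expect_equal(dim(out$phi), c(64, 64))
  set.seed(3)
  for (i in 1:10) {
    net2 <- makeNetwork(condChannels = 1, baseWidth = 4, embDim = 8,
                        seed = i)
    net2$params$headP.W[] <- stats::rnorm(4, sd = 2)
    net2$params$headP.b <- stats::rnorm(1, sd = 3)
    o <- nf(net2, matrix(stats::rnorm(256), 16, 16),
            matrix(stats::rnorm(256), 16, 16), t = sample(10, 1))
    expect_true(all(o$phi > 0))
  }
  g <- parameterGroups(net)
  expect_setequal(names(g), c("encoder", "bottleneck", "decoder", "heads"))
  expect_false(any(duplicated(unlist(g))))
  expect_setequal(unlist(g), names(net$params))
  expect_error(makeNetwork(condChannels = 0), "invalid")
})

test_that("training defaults follow the published recipe and a toy run learns", {
  cfg <- trainConfig()
  expect_equal(cfg$learningRate, 5e-5)
  expect_equal(cfg$batchSize, 64L)
  expect_equal(cfg$patience, 20L)
  expect_equal(cfg$finetuneLr, 1e-5)
  expect_equal(cfg$finetuneEpochs, 200L)

  sch <- toySchedule(20)
  net <- makeNetwork(condChannels = 1, baseWidth = 6, embDim = 8, seed = 1)
  ph <- toyPhantom(1, 32)
  ds <- lapply(1:8, function(i) {
    cl <- toyPhantom(i, 32)
    nz <- applyNoise(cl, NoiseModel(dwell = 2, seed = i))
    list(x0 = 2 * cl - 1, cond = array(2 * nz - 1, c(32, 32, 1)))
  })
  # zero epochs: unchanged weights
  fit0 <- trainDiffusion(net, ds, sch, trainConfig(maxEpochs = 0))
  expect_identical(fit0$net$params, net$params)
  expect_error(trainDiffusion(net, list(), sch), "empty")
  fit <- trainDiffusion(net, ds, sch,
                        trainConfig(learningRate = 2e-3, batchSize = 4,
                                    maxEpochs = 6, patience = Inf,
                                    seed = 1))
  expect_lt(fit$history$train[6], fit$history$train[1])
  # reproducibility of the whole loop
  fit2 <- trainDiffusion(net, ds, sch,
                         trainConfig(learningRate = 2e-3, batchSize = 4,
                                     maxEpochs = 6, patience = Inf,
                                     seed = 1))
  expect_identical(fit$net$params, fit2$net$params)
})

test_that("fine-tuning freezes the encoder bit-exactly", {
  sch <- toySchedule(20)
  net <- makeNetwork(condChannels = 1, baseWidth = 6, embDim = 8, seed = 5)
  ds <- lapply(1:4, function(i) {
    cl <- toyPhantom(40 + i, 32)
    nz <- applyNoise(cl, NoiseModel(dwell = 2, seed = i))
    list(x0 = 2 * cl - 1, cond = array(2 * nz - 1, c(32, 32, 1)))
  })
  cfg <- trainConfig(finetune = TRUE, finetuneLr = 1e-3,
                     finetuneEpochs = 3, batchSize = 4, seed = 2)
  fit <- finetuneDiffusion(net, ds, sch, cfg)
  groups <- parameterGroups(net)
  for (nm in groups$encoder)
    expect_identical(fit$net$params[[nm]], net$params[[nm]])
  changed <- vapply(c(groups$bottleneck, groups$decoder, groups$heads),
                    function(nm)
                      max(abs(fit$net$params[[nm]] - net$params[[nm]])),
                    numeric(1))
  expect_gt(max(changed), 0)
})
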