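#' Build a diffusion noise schedule
#'
#' Linear (default) or cosine ramp of per-step noise rates \eqn{\beta_t},
#' with \eqn{\alpha_t = 1 - \beta_t} and
#' \eqn{\bar\alpha_t = \prod_{i \le t} \alpha_i}. The default of T = 1000
#' linear steps from 1e-4 to 0.02 drives \eqn{\bar\alpha_T} below 0.01, so
#' the terminal state is essentially pure noise; T is configurable down to
#' a few dozen steps for desk-scale runs.
#'
#' @param Tsteps number of timesteps (>= 2).
#' @param betaMin,betaMax ramp endpoints, `0 < betaMin < betaMax < 1`.
#' @param kind `"linear"` or `"cosine"`.
#' @return a [NoiseSchedule-class].
#' @examples
#' sch <- buildSchedule(Tsteps = 2, betaMin = 0.1, betaMax = 0.2)
#' sch@alphaBar  # 0.9, 0.72
#' @export
buildSchedule <- function(Tsteps = 1000L, betaMin = 1e-4, betaMax = 0.02,
                          kind = c("linear", "cosine")) {
  kind <- match.arg(kind)
  if (Tsteps < 2) stop("Tsteps must be >= 2")
  if (!(betaMin > 0 && betaMin < betaMax && betaMax < 1))
    stop("need 0 < betaMin < betaMax < 1")
  beta <- switch(kind,
    linear = seq(betaMin, betaMax, length.out = Tsteps),
    cosine = {
      s <- 0.008
      f <- function(t) cos((t / Tsteps + s) / (1 + s) * pi / 2)^2
      ab <- f(0:Tsteps) / f(0)
      clamp(1 - ab[-1] / ab[-(Tsteps + 1)], betaMin, betaMax)
    })
  alpha <- 1 - beta
  new("NoiseSchedule", Tsteps = as.integer(Tsteps), beta = beta,
      alpha = alpha, alphaBar = cumprod(alpha), sigma2 = 1 - alpha)
}

#' Forward diffusion: noise a clean patch to timestep t
#'
#' \eqn{x_t = \sqrt{\bar\alpha_t} x_0 + \sqrt{1 - \bar\alpha_t}\,\epsilon}.
#'
#' @param x0 clean patch in model range \[-1, 1\].
#' @param t timestep in `[1, T]`.
#' @param eps standard-normal noise field, same shape as `x0`.
#' @param schedule a [NoiseSchedule-class].
#' @return the noised state `x_t`.
#' @export
forwardNoise <- function(x0, t, eps, schedule) {
  if (t < 1 || t > schedule@Tsteps)
    stop("t = ", t, " outside [1, ", schedule@Tsteps, "]")
  ab <- schedule@alphaBar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' Difficulty-aware heteroscedastic training loss
#'
#' Mean over pixels of \eqn{|\epsilon - \hat\epsilon|^2 / (2\varphi^2) +
#' \log\varphi}, where the learned difficulty map \eqn{\varphi > 0}
#' down-weights pixels that are too noisy to predict (its per-pixel
#' minimiser is \eqn{\varphi^* = |\epsilon - \hat\epsilon|}). With
#' \eqn{\varphi \equiv 1} this reduces to half the plain MSE.
#'
#' @param eps true noise field.
#' @param epsHat predicted noise field.
#' @param phi difficulty map, strictly positive, same shape.
#' @return scalar loss.
#' @export
difficultyLoss <- function(eps, epsHat, phi) {
  if (any(phi <= 0)) stop("phi must be strictly positive everywhere")
  e <- eps - epsHat
  mean(e^2 / (2 * phi^2) + log(phi))
}

# dispatch a network (trained or an oracle function) on one state
netPredict <- function(net, xt, t, cond, j = NULL, schedule = NULL) {
  if (is.function(net)) {
    out <- net(xt, t, cond, j)
    if (is.null(out$phi)) out$phi <- matrix(1, nrow(xt), ncol(xt))
    out
  } else {
    abar <- if (is.null(schedule)) NULL else schedule@alphaBar[t]
    netForward(net, xt, cond, t, j, abar = abar)
  }
}

#' One reverse diffusion step
#'
#' \eqn{x_{t-1} = (x_t - \frac{1-\alpha_t}{\sqrt{1-\bar\alpha_t}}
#' \hat\epsilon) / \sqrt{\alpha_t} + \eta} with
#' \eqn{\eta \sim N(0, (1-\alpha_t) I)} for `t > 1`; the final step
#' (`t = 1`) is deterministic so the point estimate is usable.
#'
#' @param xt current state.
#' @param t timestep in `[1, T]`.
#' @param cond condition stack (matrix or H x W x C array) in model range.
#' @param j optional layer index for channel-embedded volumetric nets.
#' @param net a trained `DiffusionNet`, or a function
#'   `(xt, t, cond, j) -> list(epsHat, phi)` serving as an oracle.
#' @param schedule a [NoiseSchedule-class].
#' @return list with `x` (the state \eqn{x_{t-1}}) and `phi` (the network's
#'   difficulty map at this step).
#' @export
reverseStep <- function(xt, t, cond, j = NULL, net, schedule) {
  if (t < 1 || t > schedule@Tsteps)
    stop("t = ", t, " outside [1, ", schedule@Tsteps, "]")
  pred <- netPredict(net, xt, t, cond, j, schedule)
  if (!all(dim(pred$epsHat) == dim(xt)))
    stop("network output shape does not match the state")
  a <- schedule@alpha[t]; ab <- schedule@alphaBar[t]
  mu <- (xt - (1 - a) / sqrt(1 - ab) * pred$epsHat) / sqrt(a)
  if (t > 1) {
    eta <- matrix(stats::rnorm(length(xt), 0, sqrt(1 - a)),
                  nrow(xt), ncol(xt))
    mu <- mu + eta
  }
  list(x = mu, phi = pred$phi)
}

#' Sample one restoration by full reverse diffusion
#'
#' Starts from standard-normal noise \eqn{x_T} and applies [reverseStep()]
#' T times, each guided by the condition stack. Deterministic given the
#' seed. The difficulty map of the final (t = 1) step is returned for
#' inspection as the terminal variance map.
#'
#' @inheritParams reverseStep
#' @param cond condition stack in model range \[-1, 1\].
#' @param seed RNG seed for `x_T` and the per-step noise.
#' @return list with `x0` (the sampled restoration, model range) and
#'   `phiFinal` (the last step's difficulty map).
#' @export
sampleRestoration <- function(cond, net, schedule, seed = 1L, j = NULL) {
  if (is.matrix(cond)) dims <- dim(cond) else dims <- dim(cond)[1:2]
  withLocalSeed(seed, {
    x <- matrix(stats::rnorm(prod(dims)), dims[1], dims[2])
    phi <- NULL
    for (t in seq(schedule@Tsteps, 1L)) {
      st <- reverseStep(x, t, cond, j, net, schedule)
      x <- st$x
      phi <- st$phi
    }
    list(x0 = x, phiFinal = phi)
  })
}

#' Training configuration
#'
#' Defaults follow the published training recipe: Adam with a constant
#' learning rate of 5e-5, batch size 64, early stopping on the validation
#' loss with 20-epoch patience; fine-tuning uses learning rate 1e-5 over
#' 200 epochs. Augmentations are horizontal/vertical flips (p = 0.5), 90
#' degree rotations and Gaussian blur of the condition (sigma 0.2–1.0,
#' p = 0.3).
#'
#' @param learningRate Adam learning rate.
#' @param batchSize samples per optimisation step.
#' @param maxEpochs epoch cap.
#' @param patience early-stopping patience in epochs (`Inf` to disable).
#' @param valFraction fraction of the dataset held out for validation when
#'   no explicit validation set is given.
#' @param augment character subset of `c("flip", "rotate90",
#'   "gaussianBlur")`.
#' @param phiLrScale learning-rate multiplier for the difficulty head
#'   (default 1, i.e. plain Adam with one constant rate for all
#'   parameters, as in the published recipe). Values below 1 make the
#'   difficulty map adapt on a slower timescale than the backbone, which
#'   can help when hard and easy examples are mixed and the map would
#'   otherwise mute the hard ones early.
#' @param finetune logical; when `TRUE` the encoder group is frozen and the
#'   fine-tuning defaults (`finetuneLr`, `finetuneEpochs`) apply.
#' @param finetuneLr,finetuneEpochs fine-tuning defaults (1e-5, 200).
#' @param seed RNG seed for batching, timesteps, noise and augmentation.
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(learningRate = 5e-5, batchSize = 64L,
                        maxEpochs = 100L, patience = 20L,
                        valFraction = 0.15,
                        augment = c("flip", "rotate90", "gaussianBlur"),
                        phiLrScale = 1,
                        finetune = FALSE, finetuneLr = 1e-5,
                        finetuneEpochs = 200L, seed = 1L) {
  stopifnot(learningRate > 0, batchSize >= 1, maxEpochs >= 0)
  structure(list(
    learningRate = learningRate, batchSize = as.integer(batchSize),
    maxEpochs = as.integer(maxEpochs), patience = patience,
    valFraction = valFraction, augment = augment,
    phiLrScale = phiLrScale,
    finetune = isTRUE(finetune), finetuneLr = finetuneLr,
    finetuneEpochs = as.integer(finetuneEpochs), seed = seed
  ), class = "TrainConfig")
}

augmentSample <- function(x0, cond, augment) {
  if ("flip" %in% augment) {
    if (stats::runif(1) < 0.5) {   # horizontal
      x0 <- x0[, rev(seq_len(ncol(x0)))]
      cond <- cond[, rev(seq_len(ncol(cond))), , drop = FALSE]
    }
    if (stats::runif(1) < 0.5) {   # vertical
      x0 <- x0[rev(seq_len(nrow(x0))), ]
      cond <- cond[rev(seq_len(nrow(cond))), , , drop = FALSE]
    }
  }
  if ("rotate90" %in% augment && nrow(x0) == ncol(x0)) {
    k <- sample.int(4L, 1L) - 1L
    rot <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])
    if (k > 0) for (i in seq_len(k)) {
      x0 <- rot(x0)
      cond <- {
        d3 <- dim(cond)[3]
        out <- array(0, c(ncol(cond), nrow(cond), d3))
        for (c in seq_len(d3)) out[, , c] <- rot(cond[, , c])
        out
      }
    }
  }
  if ("gaussianBlur" %in% augment && stats::runif(1) < 0.3) {
    sg <- stats::runif(1, 0.2, 1.0)
    for (c in seq_len(dim(cond)[3])) cond[, , c] <- gaussianBlur(cond[, , c], sg)
  }
  list(x0 = x0, cond = cond)
}

# resolve one dataset element into (x0, cond, j); volumetric samples carry a
# `targets` list from which the layer index j is drawn at train time
resolveSample <- function(s, drawJ = TRUE) {
  cond <- s$cond
  if (is.matrix(cond)) cond <- array(cond, c(dim(cond), 1L))
  if (!is.null(s$targets)) {
    R <- length(s$targets)
    jj <- if (drawJ) sample.int(R, 1L) else 1L + (R %/% 2L)
    list(x0 = s$targets[[jj]], cond = cond, j = jj)
  } else {
    list(x0 = s$x0, cond = cond, j = s$j)
  }
}

sampleLossAndGrads <- function(net, s, schedule, withGrads = TRUE,
                               fixedT = NULL, fixedEps = NULL) {
  t <- if (is.null(fixedT)) sample.int(schedule@Tsteps, 1L) else fixedT
  eps <- if (is.null(fixedEps))
    matrix(stats::rnorm(length(s$x0)), nrow(s$x0), ncol(s$x0)) else fixedEps
  xt <- forwardNoise(s$x0, t, eps, schedule)
  fwd <- netForward(net, xt, s$cond, t, s$j, abar = schedule@alphaBar[t],
                    keepCache = withGrads)
  e <- eps - fwd$epsHat
  phi <- fwd$phi
  loss <- mean(e^2 / (2 * phi^2) + log(phi))
  out <- list(loss = loss)
  if (withGrads) {
    n <- length(e)
    dEps <- -e / phi^2 / n
    dLogphi <- (1 - e^2 / phi^2) / n
    out$grads <- netBackward(net, fwd$cache, dEps, dLogphi)
  }
  out
}

#' Train the conditional diffusion network
#'
#' Minimises the difficulty-aware loss with Adam (constant learning rate).
#' Every step draws a random timestep (and, for volumetric samples, a
#' random layer index), applies augmentations, noises the target and takes
#' one gradient step per mini-batch. The checkpoint with the best
#' validation loss is returned; training stops early when the validation
#' loss has not improved for `patience` epochs.
#'
#' @param net a `DiffusionNet` from [makeNetwork()].
#' @param dataset list of samples; each is `list(x0, cond)` (patch pair,
#'   model range \[-1, 1\]) or `list(cond, targets)` for volumetric
#'   interpolation (`cond` = upper/lower layer stack, `targets` = the R
#'   intermediate layers).
#' @param config a [trainConfig()] list.
#' @param valDataset optional explicit validation set; otherwise
#'   `valFraction` of `dataset` is held out.
#' @param freeze character vector of parameter groups to freeze.
#' @return list with `net` (best checkpoint), `history` (data.frame of per
#'   epoch train/validation loss).
#' @export
trainDiffusion <- function(net, dataset, schedule, config = trainConfig(),
                           valDataset = NULL, freeze = character(0)) {
  if (length(dataset) == 0) stop("empty training dataset")
  if (config$maxEpochs == 0)
    return(list(net = net, history = data.frame(epoch = integer(0),
                                                train = numeric(0),
                                                val = numeric(0))))
  withLocalSeed(config$seed, {
    if (is.null(valDataset)) {
      nVal <- max(1L, floor(config$valFraction * length(dataset)))
      if (length(dataset) > nVal) {
        vi <- sample.int(length(dataset), nVal)
        valDataset <- dataset[vi]
        dataset <- dataset[-vi]
      } else valDataset <- dataset
    }
    # fixed validation instances so epochs are comparable
    valInst <- lapply(seq_along(valDataset), function(i) {
      s <- resolveSample(valDataset[[i]], drawJ = FALSE)
      s$t <- 1L + ((i * 7L) %% schedule@Tsteps)
      s$eps <- matrix(stats::rnorm(length(s$x0)), nrow(s$x0), ncol(s$x0))
      s
    })
    valLoss <- function(net) {
      mean(vapply(valInst, function(s)
        sampleLossAndGrads(net, s, schedule, withGrads = FALSE,
                           fixedT = s$t, fixedEps = s$eps)$loss, numeric(1)))
    }
    best <- net; bestVal <- Inf; bad <- 0L
    hist <- NULL
    for (ep in seq_len(config$maxEpochs)) {
      ord <- sample(seq_along(dataset))
      epLoss <- 0; nb <- 0L
      for (b0 in seq(1, length(ord), by = config$batchSize)) {
        idx <- ord[b0:min(b0 + config$batchSize - 1L, length(ord))]
        acc <- NULL; bl <- 0
        for (i in idx) {
          s <- resolveSample(dataset[[i]])
          ag <- augmentSample(s$x0, s$cond, config$augment)
          s$x0 <- ag$x0; s$cond <- ag$cond
          r <- sampleLossAndGrads(net, s, schedule)
          bl <- bl + r$loss
          if (is.null(acc)) acc <- r$grads
          else for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + r$grads[[nm]]
        }
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(idx)
        net <- adamStep(net, acc, config$learningRate, freeze = freeze,
                        lrScale = c(headP.W = config$phiLrScale,
                                    headP.b = config$phiLrScale))
        epLoss <- epLoss + bl / length(idx); nb <- nb + 1L
      }
      vl <- valLoss(net)
      hist <- rbind(hist, data.frame(epoch = ep, train = epLoss / nb,
                                     val = vl))
      if (vl < bestVal - 1e-9) {
        bestVal <- vl; best <- net; bad <- 0L
      } else bad <- bad + 1L
      if (is.finite(config$patience) && bad >= config$patience) break
    }
    list(net = best, history = hist)
  })
}

#' Fine-tune a pre-trained network on a new domain
#'
#' Adapts a trained network to a new sample type from as little as a single
#' tiled image pair. Only the bottleneck, decoder and head parameter groups
#' are updated; the encoder is frozen and bit-identical before and after,
#' which guards against overfitting to the small fine-tuning set. Defaults:
#' learning rate 1e-5, 200 epochs.
#'
#' @inheritParams trainDiffusion
#' @return as [trainDiffusion()].
#' @export
finetuneDiffusion <- function(net, dataset, schedule,
                              config = trainConfig(finetune = TRUE),
                              valDataset = NULL) {
  cfg <- config
  cfg$learningRate <- config$finetuneLr
  cfg$maxEpochs <- config$finetuneEpochs
  trainDiffusion(net, dataset, schedule, cfg, valDataset,
                 freeze = "encoder")
}
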