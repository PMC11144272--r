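#' Downsample a volume axially by layer removal
#'
#' Keeps only the 1-based layer indices j with `j mod f == 1` (so layers
#' 1, f+1, 2f+1, ...), multiplying the axial voxel size by f — the
#' standard way of simulating an anisotropic acquisition from an isotropic
#' one. With the default factor 6 an 8 nm isotropic stack becomes an
#' 8 x 8 x 48 nm anisotropic one.
#'
#' @param volume an [EMVolume-class].
#' @param f integer retention factor (>= 1; f = 1 is the identity).
#' @return the anisotropic [EMVolume-class].
#' @export
downsampleAxial <- function(volume, f = 6L) {
  stopifnot(is(volume, "EMVolume"))
  f <- as.integer(f)
  if (f < 1) stop("factor must be >= 1")
  if (f == 1) return(volume)
  M <- nLayers(volume)
  keep <- which(seq_len(M) %% f == 1L)
  vs <- voxelSize(volume)
  EMVolume(volume@data[keep, , , drop = FALSE],
           voxelSize = c(vs[1] * f, vs[2], vs[3]))
}

#' Build volumetric training samples along z (isotropic training volume)
#'
#' For every valid upper layer index u (1-based), the condition is the
#' layer pair (c^u, c^(u+R+1)) and the targets are the R intermediate
#' layers u+1, ..., u+R; at train time one target index j in \[1, R\] is
#' drawn uniformly per iteration. Requires an isotropic training volume
#' with at least R + 2 layers.
#'
#' @param volume isotropic [EMVolume-class].
#' @param R interpolation count; defaults to the volume's derived value.
#' @return list of samples `list(cond = H x W x 2 array, targets = list of
#'   R matrices, axis = "z")`, intensities mapped to model range \[-1, 1\]
#'   with a per-volume (not per-slice) scale.
#' @export
buildTrainingSamplesI <- function(volume, R = interpolationCount(volume)) {
  stopifnot(is(volume, "EMVolume"))
  R <- as.integer(R)
  if (R < 1)
    stop("R = ", R, " yields no intermediate layers to learn (empty dataset)")
  M <- nLayers(volume)
  if (M < R + 2)
    stop("volume has ", M, " layers; need at least R + 2 = ", R + 2)
  v <- toModelRange(volume@data)
  lapply(seq_len(M - R - 1L), function(u) {
    cond <- array(0, c(dim(v)[2], dim(v)[3], 2L))
    cond[, , 1] <- v[u, , ]
    cond[, , 2] <- v[u + R + 1L, , ]
    list(cond = cond,
         targets = lapply(seq_len(R), function(j) v[u + j, , ]),
         axis = "z", u = u)
  })
}

#' Build volumetric training samples along y (anisotropic training volume)
#'
#' Identical index arithmetic to the z-axis construction, but the slices
#' are XZ views extracted along the y axis of the anisotropic volume — the
#' lateral axis plays the role of the missing axial one, so no isotropic
#' training data is needed. These views carry the line artifacts of the
#' anisotropic stack; training tolerates them. The recommended epoch cap
#' for this variant is 1200 (see [vemATrainConfig()]), as longer training
#' overfits to the artifacts.
#'
#' @param volume anisotropic [EMVolume-class].
#' @param R interpolation count.
#' @return list of samples as in [buildTrainingSamplesI()] but with slices
#'   of shape (Z, X) and `axis = "y"`.
#' @export
buildTrainingSamplesA <- function(volume, R) {
  stopifnot(is(volume, "EMVolume"))
  R <- as.integer(R)
  if (R < 1) stop("R must be >= 1")
  Y <- dim(volume@data)[2]
  if (Y < R + 2)
    stop("y extent ", Y, " too small; need at least R + 2 = ", R + 2)
  v <- toModelRange(volume@data)
  lapply(seq_len(Y - R - 1L), function(u) {
    cond <- array(0, c(dim(v)[1], dim(v)[3], 2L))
    cond[, , 1] <- v[, u, ]        # XZ view, shape (Z, X)
    cond[, , 2] <- v[, u + R + 1L, ]
    list(cond = cond,
         targets = lapply(seq_len(R), function(j) v[, u + j, ]),
         axis = "y", u = u)
  })
}

#' Default training configuration for the anisotropic-only variant
#'
#' As [trainConfig()] but with the 1200-epoch cap that prevents
#' overfitting to the line artifacts of XZ training views.
#'
#' @param ... overrides passed to [trainConfig()].
#' @export
vemATrainConfig <- function(...) {
  cfg <- trainConfig(...)
  dots <- list(...)
  if (is.null(dots$maxEpochs)) cfg$maxEpochs <- 1200L
  cfg
}

#' Reconstruct an isotropic volume from an anisotropic one
#'
#' Traverses every pair of adjacent layers (c^u, c^(u+1)) of the M-layer
#' input and generates the R intermediate layers between them with the
#' channel-embedded diffusion network, j = 1..R, averaging K draws per
#' layer (K = 2 by default). The generated layers are interleaved with the
#' originals, giving M + (M-1) * R output layers, and the axial voxel size
#' is divided by R + 1. Per generated layer, the ensemble SD yields an
#' uncertainty report.
#'
#' @param volume anisotropic [EMVolume-class] with M >= 2 layers.
#' @param net trained `DiffusionNet` (2 condition channels, channel
#'   embedding) or an oracle function.
#' @param schedule a [NoiseSchedule-class].
#' @param R interpolation count; defaults to the volume's derived value.
#' @param K draws per generated layer (default 2).
#' @param tau reliability threshold for the per-layer reports.
#' @param seed base seed; per-layer seeds are derived deterministically.
#' @return list with `volume` (the isotropic [EMVolume-class]) and
#'   `reports` (list of [UncertaintyReport-class], one per generated
#'   layer, named by output layer index).
#' @export
inferIsotropic <- function(volume, net, schedule,
                           R = interpolationCount(volume), K = 2L,
                           tau = 0.12, seed = 1L) {
  stopifnot(is(volume, "EMVolume"))
  M <- nLayers(volume)
  if (M < 2) stop("volume must have at least 2 layers")
  R <- as.integer(R)
  if (R == 0) return(list(volume = volume, reports = list()))
  d <- dim(volume@data)
  outM <- M + (M - 1L) * R
  out <- array(0, c(outM, d[2], d[3]))
  reports <- list()
  v <- toModelRange(volume@data)
  sliceGrid <- makePatchGrid(c(d[2], d[3]),
                             patchSize = min(256L, d[2], d[3]),
                             stride = min(196L, d[2], d[3]))
  for (u in seq_len(M)) out[(u - 1L) * (R + 1L) + 1L, , ] <- volume@data[u, , ]
  for (u in seq_len(M - 1L)) {
    cond <- array(0, c(d[2], d[3], 2L))
    cond[, , 1] <- v[u, , ]
    cond[, , 2] <- v[u + 1L, , ]
    for (j in seq_len(R)) {
      seeds <- seed + ((u - 1L) * R + (j - 1L)) * K + seq_len(K) - 1L
      ens <- predictEnsemble(cond, net, schedule, K = K, seeds = seeds, j = j)
      outIdx <- (u - 1L) * (R + 1L) + 1L + j
      out[outIdx, , ] <- clamp01(fromModelRange(ens@mean))
      if (K >= 2) {
        samp01 <- ens@samples
        for (m in seq_len(K))
          samp01[, , m] <- clamp01(fromModelRange(ens@samples[, , m]))
        stacks <- lapply(seq_len(nrow(sliceGrid@origins)), function(i) {
          o <- sliceGrid@origins[i, ]; ps <- sliceGrid@patchSize
          samp01[(o[1] + 1):(o[1] + ps), (o[2] + 1):(o[2] + ps), , drop = FALSE]
        })
        reports[[as.character(outIdx)]] <-
          assessImage(stacks, sliceGrid, tau = tau)
      }
    }
  }
  vs <- voxelSize(volume)
  list(volume = EMVolume(out, voxelSize = c(vs[1] / (R + 1L), vs[2], vs[3])),
       reports = reports)
}

#' Cubic-interpolation baseline for axial upsampling
#'
#' Per-(y, x) column cubic convolution interpolation of the anisotropic
#' stack onto the fine axial grid (the classical intensity-space baseline
#' that learned interpolation is compared against). Output geometry
#' matches [inferIsotropic()]: M + (M-1) * (factor-1) layers with the
#' original layers preserved exactly.
#'
#' @param volume anisotropic [EMVolume-class] with M >= 4 layers.
#' @param factor axial upsampling factor (original spacing / target
#'   spacing); `factor - 1` layers are inserted per gap.
#' @return interpolated [EMVolume-class].
#' @export
cubicBaseline <- function(volume, factor = 6L) {
  stopifnot(is(volume, "EMVolume"))
  M <- nLayers(volume)
  if (M < 4) stop("cubic interpolation needs at least 4 layers")
  factor <- as.integer(factor)
  R <- factor - 1L
  d <- dim(volume@data)
  outM <- M + (M - 1L) * R
  out <- array(0, c(outM, d[2], d[3]))
  vdat <- volume@data
  layer <- function(i) vdat[clamp(i, 1L, M), , ]
  for (u in seq_len(M)) out[(u - 1L) * (R + 1L) + 1L, , ] <- vdat[u, , ]
  if (R > 0) for (u in seq_len(M - 1L)) for (j in seq_len(R)) {
    fr <- j / (R + 1)
    w <- keysKernel(fr - c(-1, 0, 1, 2))
    sl <- w[1] * layer(u - 1L) + w[2] * layer(u) +
      w[3] * layer(u + 1L) + w[4] * layer(u + 2L)
    out[(u - 1L) * (R + 1L) + 1L + j, , ] <- sl / sum(w)
  }
  vs <- voxelSize(volume)
  EMVolume(clamp01(out), voxelSize = c(vs[1] / (R + 1L), vs[2], vs[3]))
}
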