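#' Generate a synthetic 2D EM phantom
#'
#' Renders an EM-like grayscale micrograph: elliptical organelles bounded by
#' dark membranes with internal cristae-like lamellae, curvilinear membrane
#' strands, and a low-frequency background texture. Entirely deterministic in
#' the spec (seed included), so paired noisy/clean and drifted acquisitions
#' with exact ground truth can be produced for testing every downstream
#' stage without any real data.
#'
#' @param spec a [PhantomSpec-class].
#' @return numeric matrix `height x width` with values in \[0, 1\].
#' @examples
#' img <- generatePhantom2D(PhantomSpec(height = 96, width = 96, seed = 7))
#' range(img)
#' @export
generatePhantom2D <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  h <- as.integer(spec@height); w <- as.integer(spec@width)
  if (h < 64 || w < 64)
    stop("phantom dimensions must be >= 64 pixels (got ", h, " x ", w, ")")
  withLocalSeed(spec@seed, {
    img <- phantomBackground(h, w, spec@textureScale)
    n <- as.integer(spec@nOrganelles)
    if (n > 0) {
      # membrane strands: one per two organelles, so the organelle-free
      # degenerate phantom stays featureless
      img <- drawMembraneStrands(img, max(0L, n %/% 2L),
                                 spec@membraneThickness)
      img <- drawOrganelles(img, n, spec@membraneThickness)
    }
    lo <- spec@intensityRange[1]; hi <- spec@intensityRange[2]
    clamp01(lo + (hi - lo) * clamp01(img))
  })
}

phantomBackground <- function(h, w, textureScale) {
  if (!is.finite(textureScale)) return(matrix(0.5, h, w))
  z <- matrix(stats::rnorm(h * w), h, w)
  z <- gaussianBlur(z, textureScale / 3)
  s <- stats::sd(z)
  if (s > 0) z <- z / s
  0.5 + 0.08 * z
}

drawMembraneStrands <- function(img, nStrands, thickness) {
  if (nStrands == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  stamp <- matrix(0, h, w)
  for (s in seq_len(nStrands)) {
    len <- round(1.2 * max(h, w))
    y <- stats::runif(1, 1, h); x <- stats::runif(1, 1, w)
    theta <- stats::runif(1, 0, 2 * pi)
    curv <- gaussianBlur(matrix(stats::rnorm(len), len, 1), 8)[, 1] * 0.6
    for (i in seq_len(len)) {
      theta <- theta + curv[i] * 0.15
      y <- y + sin(theta); x <- x + cos(theta)
      if (y < 1 || y > h || x < 1 || x > w) break
      stamp[round(y), round(x)] <- 1
    }
  }
  brush <- EBImage::makeBrush(2 * floor(thickness / 2) + 1, shape = "disc")
  stamp <- EBImage::dilate(stamp, brush)
  img[stamp > 0] <- 0.15
  img
}

drawOrganelles <- function(img, n, thickness) {
  h <- nrow(img); w <- ncol(img)
  cc <- matrix(rep(seq_len(w), each = h), h, w)
  rr <- matrix(rep(seq_len(h), times = w), h, w)
  minAx <- max(6, 3 * thickness); maxAx <- min(h, w) / 5
  for (k in seq_len(n)) {
    cy <- stats::runif(1, 0.15 * h, 0.85 * h)
    cx <- stats::runif(1, 0.15 * w, 0.85 * w)
    a <- stats::runif(1, minAx, maxAx)
    b <- stats::runif(1, minAx, maxAx)
    ang <- stats::runif(1, 0, pi)
    bright <- stats::runif(1, 0.12, 0.22)
    xr <- (cc - cx) * cos(ang) + (rr - cy) * sin(ang)
    yr <- -(cc - cx) * sin(ang) + (rr - cy) * cos(ang)
    s <- sqrt((xr / a)^2 + (yr / b)^2)
    interior <- s < 1
    img[interior] <- clamp01(img[interior] + bright)
    # cristae-like internal lamellae: dark stripes across the interior
    spacing <- max(3, 3 * thickness)
    stripes <- interior & s < 0.8 &
      (sin(2 * pi * xr / spacing + stats::runif(1, 0, 2 * pi)) > 0.55)
    img[stripes] <- 0.2
    # bounding membrane, `thickness` px wide in the normal direction
    band <- abs(s - 1) < thickness / (a + b)
    img[band] <- 0.12
  }
  img
}

#' Apply dwell-time dependent acquisition noise
#'
#' Samples, per pixel, `Poisson(shotGain * dwell * clean) / (shotGain *
#' dwell) + Normal(0, readSigma^2 / dwell)` and clips to \[0, 1\]. The noise
#' standard deviation on a flat image therefore scales as `dwell^(-1/2)`,
#' emulating paired acquisitions taken at different scan speeds.
#'
#' @param clean numeric matrix in \[0, 1\].
#' @param model a [NoiseModel-class]; `dwell` must be positive.
#' @return noisy image, same shape, clipped to \[0, 1\].
#' @export
applyNoise <- function(clean, model) {
  stopifnot(is(model, "NoiseModel"))
  if (model@dwell <= 0) stop("dwell must be > 0 (got ", model@dwell, ")")
  if (min(clean) < 0 || max(clean) > 1)
    stop("clean image must lie in [0, 1]")
  withLocalSeed(model@seed, {
    g <- model@shotGain * model@dwell
    lam <- g * c(clean)
    shot <- numeric(length(lam))
    big <- lam > 1e7  # normal approximation where rpois would overflow
    if (any(!big)) shot[!big] <- stats::rpois(sum(!big), lam[!big])
    if (any(big)) shot[big] <- stats::rnorm(sum(big), lam[big], sqrt(lam[big]))
    out <- shot / g + stats::rnorm(length(lam), 0,
                                   model@readSigma / sqrt(model@dwell))
    matrix(clamp01(out), nrow(clean), ncol(clean))
  })
}

#' Simulate paired short-dwell / long-dwell acquisitions
#'
#' Generates phantom scenes and acquires each twice with the
#' dwell-dependent noise model: a fast raw scan at `dwell` and a reference
#' scan at `referenceDwellRatio * dwell`. The default ratio of 18 is the
#' acquisition-speedup regime the denoiser targets — restoring the fast
#' scan to reference quality means an 18-fold reduction in acquisition
#' time.
#'
#' @param n number of pairs.
#' @param side image side length in pixels.
#' @param dwell dwell of the raw (noisy) acquisition.
#' @param referenceDwellRatio reference dwell as a multiple of `dwell`
#'   (default 18).
#' @param drift optional [DriftModel-class] applied to the raw acquisition
#'   (the reference stays in the scene frame).
#' @param seed base seed; scene i uses `seed + i`.
#' @return list of `list(clean, reference, raw)` triples: the noise-free
#'   scene, the long-dwell reference and the short-dwell raw image.
#' @export
simulateDenoisePairs <- function(n, side = 128, dwell = 1,
                                 referenceDwellRatio = 18, drift = NULL,
                                 seed = 1L) {
  lapply(seq_len(n), function(i) {
    cl <- generatePhantom2D(PhantomSpec(height = side, width = side,
                                        seed = seed + i))
    ref <- applyNoise(cl, NoiseModel(dwell = referenceDwellRatio * dwell,
                                     seed = seed + 20000L + i))
    raw <- cl
    if (!is.null(drift)) raw <- applyDrift(raw, drift)$image
    raw <- applyNoise(raw, NoiseModel(dwell = dwell,
                                      seed = seed + 10000L + i))
    list(clean = cl, reference = ref, raw = raw)
  })
}

#' Apply a known drift to an image
#'
#' Warps the image by the model homography, then by a smooth random
#' displacement field whose maximum magnitude equals
#' `smoothFieldAmplitude` pixels — the global-plus-local misalignment that
#' two-stage registration must undo. The true transforms are returned
#' alongside the drifted image so registration accuracy can be scored
#' against ground truth.
#'
#' @param image numeric matrix.
#' @param model a [DriftModel-class].
#' @return list with `image` (drifted), `homography` (the 3x3 used,
#'   mapping target (x, y, 1) to source), and `flowField`
#'   (height x width x 2 array of (dy, dx), zero when amplitude is 0).
#' @export
applyDrift <- function(image, model) {
  stopifnot(is(model, "DriftModel"))
  if (!is.matrix(image)) stop("image must be a 2D matrix")
  h <- nrow(image); w <- ncol(image)
  field <- array(0, c(h, w, 2))
  if (model@smoothFieldAmplitude > 0) {
    field <- withLocalSeed(model@seed, {
      f <- array(0, c(h, w, 2))
      for (k in 1:2)
        f[, , k] <- gaussianBlur(matrix(stats::rnorm(h * w), h, w),
                                 model@smoothFieldScale / 3)
      mag <- sqrt(f[, , 1]^2 + f[, , 2]^2)
      m <- max(mag)
      if (m > 0) f <- f * (model@smoothFieldAmplitude / m)
      f
    })
  }
  identityH <- isTRUE(all.equal(model@homography, diag(3),
                                tolerance = 1e-12))
  out <- if (identityH && model@smoothFieldAmplitude == 0) image
  else clamp(warpHomography(image, model@homography,
                            flow = if (model@smoothFieldAmplitude > 0) field),
             min(image), max(image))  # cubic resampling may overshoot
  list(image = out, homography = model@homography, flowField = field)
}

#' Generate a synthetic isotropic EM phantom volume
#'
#' A 3D stack of membrane-bounded tubes whose centers and radii drift
#' smoothly along z over a smoothly varying background, giving the
#' axially-continuous structure of real volume-EM data: adjacent slices
#' correlate strongly, distant slices less, and structural edges move
#' laterally between slices — exactly the situation in which learned axial
#' interpolation can outperform intensity-space interpolation. All three
#' voxel sizes are set equal (8 nm by default, matching common FIB-SEM
#' acquisitions).
#'
#' @param spec a [PhantomSpec-class]; `depth` must be >= 16.
#' @param voxelNm isotropic voxel edge length in nm (default 8).
#' @return an [EMVolume-class] with data dim (depth, height, width).
#' @export
generatePhantomVolume <- function(spec, voxelNm = 8) {
  stopifnot(is(spec, "PhantomSpec"))
  d <- as.integer(spec@depth)
  h <- as.integer(spec@height); w <- as.integer(spec@width)
  if (d < 16) stop("volume depth must be >= 16 (got ", d, ")")
  withLocalSeed(spec@seed, {
    nT <- max(1L, as.integer(spec@nOrganelles))
    thick <- spec@membraneThickness
    # smoothly drifting tube tracks
    cy <- matrix(0, d, nT); cx <- matrix(0, d, nT); rad <- matrix(0, d, nT)
    for (k in seq_len(nT)) {
      cy[, k] <- stats::runif(1, 0.2 * h, 0.8 * h) +
        cumsum(gaussianBlur(matrix(stats::rnorm(d), d, 1), 2)[, 1] * 0.9)
      cx[, k] <- stats::runif(1, 0.2 * w, 0.8 * w) +
        cumsum(gaussianBlur(matrix(stats::rnorm(d), d, 1), 2)[, 1] * 0.9)
      r0 <- stats::runif(1, max(4, 2 * thick), min(h, w) / 6)
      rad[, k] <- r0 * (1 + 0.25 * sin(2 * pi * seq_len(d) / d +
                                       stats::runif(1, 0, 2 * pi)))
    }
    # background: 2D textures at z-knots, linearly blended along z
    nKnot <- 4L
    knots <- lapply(seq_len(nKnot), function(i)
      phantomBackground(h, w, spec@textureScale))
    kz <- seq(1, d, length.out = nKnot)
    cc <- matrix(rep(seq_len(w), each = h), h, w)
    rr <- matrix(rep(seq_len(h), times = w), h, w)
    vol <- array(0, c(d, h, w))
    for (z in seq_len(d)) {
      ki <- findInterval(z, kz, rightmost.closed = TRUE)
      ki <- clamp(ki, 1L, nKnot - 1L)
      fr <- (z - kz[ki]) / (kz[ki + 1] - kz[ki])
      sl <- (1 - fr) * knots[[ki]] + fr * knots[[ki + 1]]
      for (k in seq_len(nT)) {
        dist <- sqrt((rr - cy[z, k])^2 + (cc - cx[z, k])^2)
        sl[dist < rad[z, k] - thick / 2] <- 0.78
        sl[abs(dist - rad[z, k]) < thick / 2] <- 0.12
      }
      lo <- spec@intensityRange[1]; hi <- spec@intensityRange[2]
      vol[z, , ] <- clamp01(lo + (hi - lo) * clamp01(sl))
    }
    EMVolume(vol, voxelSize = rep(voxelNm, 3))
  })
}
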