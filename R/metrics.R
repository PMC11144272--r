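# Quantitative image-quality metrics: FSIM, Fourier ring correlation,
# single-image spectral resolution, IoU, power spectra.

fftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c((h %/% 2 + 1):h, 1:(h %/% 2)), c((w %/% 2 + 1):w, 1:(w %/% 2))]
}

fftFreqGrid <- function(h, w) {
  fy <- c(seq(0, floor(h / 2)), seq(-(ceiling(h / 2) - 1), -1)) / h
  fx <- c(seq(0, floor(w / 2)), seq(-(ceiling(w / 2) - 1), -1)) / w
  FY <- matrix(rep(fy, times = w), h, w)
  FX <- matrix(rep(fx, each = h), h, w)
  list(r = sqrt(FY^2 + FX^2), theta = atan2(FY, FX))
}

# log-Gabor filter bank; returns list over orientations of lists over scales
logGaborBank <- function(h, w, nScale = 4, nOrient = 4, minWaveLength = 6,
                         mult = 2, sigmaOnf = 0.55, dThetaOnSigma = 1.2) {
  g <- fftFreqGrid(h, w)
  r <- g$r; r[1, 1] <- 1
  lp <- 1 / (1 + (g$r / 0.45)^30)  # low-pass to kill the corner frequencies
  radial <- lapply(seq_len(nScale), function(s) {
    f0 <- 1 / (minWaveLength * mult^(s - 1))
    rf <- exp(-(log(r / f0))^2 / (2 * log(sigmaOnf)^2)) * lp
    rf[1, 1] <- 0
    rf
  })
  thetaSigma <- pi / nOrient / dThetaOnSigma
  lapply(seq_len(nOrient), function(o) {
    ang <- (o - 1) * pi / nOrient
    ds <- sin(g$theta) * cos(ang) - cos(g$theta) * sin(ang)
    dc <- cos(g$theta) * cos(ang) + sin(g$theta) * sin(ang)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * thetaSigma^2))
    lapply(radial, function(rf) rf * spread)
  })
}

# phase congruency map (energy over total amplitude, summed across
# orientations), as used by the feature-similarity index
phaseCongruency <- function(img, bank) {
  Fimg <- stats::fft(img)
  energyAll <- 0; anAll <- 0
  for (o in seq_along(bank)) {
    sumE <- 0; sumO <- 0; sumAn <- 0
    for (s in seq_along(bank[[o]])) {
      eo <- stats::fft(Fimg * bank[[o]][[s]], inverse = TRUE) / length(img)
      sumE <- sumE + Re(eo)
      sumO <- sumO + Im(eo)
      sumAn <- sumAn + Mod(eo)
    }
    energyAll <- energyAll + sqrt(sumE^2 + sumO^2)
    anAll <- anAll + sumAn
  }
  energyAll / (anAll + 1e-8)
}

scharrGradient <- function(img) {
  kx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, 3) / 16
  pad <- function(m) {
    m <- rbind(m[1, ], m, m[nrow(m), ])
    cbind(m[, 1], m, m[, ncol(m)])
  }
  p <- pad(img)
  h <- nrow(img); w <- ncol(img)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2) {
    blk <- p[(1:h) + dy, (1:w) + dx]
    gx <- gx + kx[dy + 1, dx + 1] * blk
    gy <- gy + kx[dx + 1, dy + 1] * blk
  }
  sqrt(gx^2 + gy^2)
}

meanPool <- function(img, f) {
  if (f <= 1) return(img)
  h <- f * (nrow(img) %/% f); w <- f * (ncol(img) %/% f)
  img <- img[seq_len(h), seq_len(w)]
  out <- matrix(0, h %/% f, w %/% f)
  for (dy in seq_len(f)) for (dx in seq_len(f))
    out <- out + img[seq(dy, h, f), seq(dx, w, f)]
  out / f^2
}

#' Feature similarity index (FSIM)
#'
#' Combines phase-congruency similarity with gradient-magnitude similarity,
#' weighted by the maximum phase congruency, using the published default
#' constants (T1 = 0.85, T2 = 160 on a 0–255 intensity scale; four
#' log-Gabor scales and orientations). Used here in place of PSNR because
#' residual noise in ground-truth EM acquisitions corrupts pixelwise error
#' metrics.
#'
#' @param x,y grayscale matrices of the same shape (any common intensity
#'   scale; rescaled to 0–255 internally).
#' @return similarity score in \[0, 1\]; 1 for identical images.
#' @export
fsim <- function(x, y) {
  if (!all(dim(x) == dim(y))) stop("images must share dimensions")
  x <- x * 255; y <- y * 255
  f <- max(1, round(min(dim(x)) / 256))
  x <- meanPool(x, f); y <- meanPool(y, f)
  bank <- logGaborBank(nrow(x), ncol(x))
  pc1 <- phaseCongruency(x, bank)
  pc2 <- phaseCongruency(y, bank)
  g1 <- scharrGradient(x); g2 <- scharrGradient(y)
  T1 <- 0.85; T2 <- 160
  sPC <- (2 * pc1 * pc2 + T1) / (pc1^2 + pc2^2 + T1)
  sG <- (2 * g1 * g2 + T2) / (g1^2 + g2^2 + T2)
  pcm <- pmax(pc1, pc2)
  sum(sPC * sG * pcm) / sum(pcm)
}

#' Fourier ring correlation between two images
#'
#' Normalized cross-correlation of the Fourier coefficients of two images
#' per radial frequency ring. The cutoff is the first crossing of the 1/7
#' criterion; the implied resolution is `pixelSize / cutoff`.
#'
#' @param x,y equal square matrices.
#' @param ringWidth ring width in frequency-grid pixels.
#' @param pixelSize physical pixel size (e.g. nm) for the resolution.
#' @return list of class `FRCCurve`: `freq` (cycles/pixel, increasing),
#'   `correlation` per ring, `cutoff`, `resolution`.
#' @export
frc <- function(x, y, ringWidth = 1, pixelSize = 1) {
  if (!all(dim(x) == dim(y)) || nrow(x) != ncol(x))
    stop("images must be equal and square")
  n <- nrow(x)
  F1 <- stats::fft(x - mean(x)); F2 <- stats::fft(y - mean(y))
  g <- fftFreqGrid(n, n)
  ringIdx <- floor(g$r * n / ringWidth)
  maxRing <- floor(n / 2 / ringWidth)
  keep <- ringIdx <= maxRing
  num <- Re(F1 * Conj(F2)); p1 <- Mod(F1)^2; p2 <- Mod(F2)^2
  sNum <- tapply(num[keep], ringIdx[keep], sum)
  sP1 <- tapply(p1[keep], ringIdx[keep], sum)
  sP2 <- tapply(p2[keep], ringIdx[keep], sum)
  corr <- as.numeric(sNum / sqrt(sP1 * sP2))
  corr[!is.finite(corr)] <- 0
  rings <- as.integer(names(sNum))
  freq <- rings * ringWidth / n
  ord <- order(freq)
  freq <- freq[ord]; corr <- corr[ord]
  corr[freq == 0] <- if (stats::sd(x) > 0 && stats::sd(y) > 0) corr[freq == 0] else 1
  thr <- 1 / 7
  below <- which(corr < thr & freq > 0)
  cutoff <- if (length(below) == 0) max(freq) else {
    i <- below[1]
    if (i == 1) freq[1]
    else freq[i - 1] + (freq[i] - freq[i - 1]) *
      (corr[i - 1] - thr) / max(corr[i - 1] - corr[i], 1e-12)
  }
  structure(list(freq = freq, correlation = corr, cutoff = cutoff,
                 resolution = pixelSize / cutoff),
            class = "FRCCurve")
}

#' @export
print.FRCCurve <- function(x, ...) {
  cat(sprintf("FRCCurve: %d rings, cutoff %.4f cycles/px, resolution %.3g\n",
              length(x$freq), x$cutoff, x$resolution))
  invisible(x)
}

#' Single-image spectral resolution estimate
#'
#' Decorrelation-style analysis: the image spectrum is cross-correlated
#' with its phase-normalized counterpart restricted to increasing radial
#' frequency masks. Within the support of real structure each additional
#' ring raises the correlation appreciably; the cutoff is the last mask
#' radius whose gain is still 10% of the largest single-ring gain, and
#' resolution = `pixelSize / cutoff`. Lower
#' values mean finer detail. Smoothing an image strictly worsens (raises)
#' its resolution value.
#'
#' @param x grayscale matrix (non-constant).
#' @param pixelSize physical pixel size.
#' @param nRadii number of mask radii on the curve (default 50).
#' @return list: `radii` (cycles/pixel), `curve`, `cutoff`, `resolution`.
#' @export
resolutionEstimate <- function(x, pixelSize = 1, nRadii = 50) {
  if (stats::sd(x) == 0)
    stop("resolution is undefined for a constant image")
  Fx <- stats::fft(x - mean(x))
  In <- Fx / pmax(Mod(Fx), 1e-12)
  g <- fftFreqGrid(nrow(x), ncol(x))
  radii <- seq(0.02, 0.5, length.out = nRadii)
  aF <- Mod(Fx)
  sumF2 <- sum(aF^2)
  curve <- vapply(radii, function(rr) {
    m <- g$r <= rr
    nPix <- sum(m)
    if (nPix < 2) return(0)
    num <- sum(aF[m])          # Re(F * Conj(In)) = |F| on the mask
    num / sqrt(sumF2 * nPix)
  }, numeric(1))
  # knee rule: within the support of real structure every additional ring
  # raises the correlation appreciably; past the cutoff the gains collapse.
  # The cutoff is the last radius whose gain is still >= 10% of the largest
  # single-ring gain.
  inc <- diff(curve)   # ring-to-ring gains; the DC ring is not a gain
  pk <- 1L + max(which(inc >= 0.1 * max(inc)))
  cutoff <- radii[pk]
  list(radii = radii, curve = curve, cutoff = cutoff,
       resolution = pixelSize / cutoff)
}

#' Resolution ratio of ground truth over prediction
#'
#' `resolutionEstimate(gt) / resolutionEstimate(pred)`: values above 1 mean
#' the prediction resolves finer detail than the reference, below 1 that it
#' is smoother.
#'
#' @param gt,pred matrices of the same shape.
#' @param pixelSize physical pixel size.
#' @return scalar ratio.
#' @export
resolutionRatio <- function(gt, pred, pixelSize = 1) {
  if (!all(dim(gt) == dim(pred))) stop("images must share dimensions")
  resolutionEstimate(gt, pixelSize)$resolution /
    resolutionEstimate(pred, pixelSize)$resolution
}

#' Intersection over union of binary masks
#'
#' `|A intersect B| / |A union B|` with optional morphological
#' post-processing (opening removes small false-positive specks, closing
#' fills small holes) applied to both masks before scoring. Two empty
#' masks score 1 by convention.
#'
#' @param maskA,maskB binary (logical or 0/1) matrices of the same shape.
#' @param postprocess one of `"none"`, `"open"`, `"close"`, `"openclose"`.
#' @param brushSize odd disc diameter for the structuring element.
#' @return score in \[0, 1\].
#' @export
iou <- function(maskA, maskB, postprocess = c("none", "open", "close",
                                              "openclose"),
                brushSize = 3L) {
  postprocess <- match.arg(postprocess)
  if (!all(dim(maskA) == dim(maskB))) stop("masks must share dimensions")
  a <- (maskA > 0) * 1; b <- (maskB > 0) * 1
  if (postprocess != "none") {
    brush <- EBImage::makeBrush(brushSize, shape = "disc")
    post <- function(m) {
      if (postprocess %in% c("open", "openclose"))
        m <- EBImage::dilate(EBImage::erode(m, brush), brush)
      if (postprocess %in% c("close", "openclose"))
        m <- EBImage::erode(EBImage::dilate(m, brush), brush)
      m
    }
    a <- post(a); b <- post(b)
  }
  uni <- sum(a | b)
  if (uni == 0) return(1)
  sum(a & b) / uni
}

#' Centered log power spectrum
#'
#' For qualitative inspection of restoration outputs: regression-style
#' restorations approximate a posterior mean and leave a characteristic
#' horizontal/vertical "smoothness cross" in this view, which
#' sampling-based restorations avoid.
#'
#' @param x grayscale matrix.
#' @return matrix `log1p(|F|^2)`, zero frequency at the center.
#' @export
powerSpectrum <- function(x) {
  log1p(Mod(fftshift2(stats::fft(x)))^2)
}
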