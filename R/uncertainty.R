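#' Uncertainty value of one patch
#'
#' The patch's scalar uncertainty U is the `q`-th percentile (linear
#' interpolation between closest order statistics) of its per-pixel
#' ensemble SD map. With the default q = 99 the top 1% of uncertainty
#' pixels are disregarded: isolated outliers and high-contrast structural
#' boundaries (organelle membranes) inflate the SD without indicating a
#' wrong prediction, so the maximum is deliberately not used.
#'
#' @param delta per-pixel SD map of one patch (from K min-max normalized
#'   samples).
#' @param q percentile in (0, 100\], default 99.
#' @return scalar U >= 0.
#' @export
patchUncertainty <- function(delta, q = 99) {
  if (length(delta) == 0) stop("empty patch")
  linearPercentile(c(delta), q)
}

#' Assess the reliability of a patchwise prediction
#'
#' For each patch the K sampled restorations are min-max normalized within
#' the patch (enhancing local contrast and making U invariant to affine
#' intensity rescaling), their per-pixel SD is computed with denominator
#' K - 1, and the patch uncertainty value U is its `q`-th percentile.
#' A patch with U > tau is flagged unreliable; the whole image is flagged
#' iff any patch is.
#'
#' @param sampleStacks list (one element per grid patch, in grid order) of
#'   H x W x K arrays of the K sampled restorations, raw intensity scale.
#' @param grid the [PatchGrid-class] of the tiling.
#' @param tau reliability threshold, default 0.12.
#' @param q percentile, default 99.
#' @return an [UncertaintyReport-class].
#' @export
assessImage <- function(sampleStacks, grid, tau = 0.12, q = 99) {
  if (length(sampleStacks) != nrow(grid@origins))
    stop("one sample stack per grid patch required")
  K <- dim(sampleStacks[[1]])[3]
  if (K < 2)
    stop("cannot assess uncertainty with K = ", K,
         ": the ensemble SD requires at least 2 samples")
  U <- vapply(sampleStacks, function(st) {
    for (m in seq_len(dim(st)[3])) st[, , m] <- minMaxNormalize(st[, , m])
    patchUncertainty(ensembleStdFast(st), q)
  }, numeric(1))
  flags <- U > tau
  new("UncertaintyReport", patchValues = U, tau = tau, percentile = q,
      patchFlags = flags, imageFlag = any(flags),
      origins = grid@origins)
}

#' Calibrate the reliability threshold from scored predictions
#'
#' Given uncertainty values U and an external quality score per
#' prediction, the score distribution is histogrammed (Gaussian-smoothed),
#' the valley between its two largest modes located, and tau set to the
#' mean U of the predictions falling within half a bin of the valley —
#' the samples at the boundary between confidently-good and
#' confidently-bad predictions. The published calibration of this
#' procedure on a multi-noise-level mouse cortex dataset gave tau = 0.12,
#' the package default; users are encouraged to recalibrate on their own
#' data.
#'
#' @param U numeric vector of patch/image uncertainty values.
#' @param score numeric vector of quality scores (same length; any metric
#'   where the two quality regimes separate, e.g. a perceptual distance).
#' @param bins histogram bin count (default 32).
#' @param smoothSigma Gaussian smoothing of the histogram, in bins.
#' @param minSamples minimum number of scored predictions required.
#' @return scalar tau.
#' @export
calibrateThreshold <- function(U, score, bins = 32L, smoothSigma = 1,
                               minSamples = 20L) {
  stopifnot(length(U) == length(score))
  if (length(U) < minSamples)
    stop("need at least ", minSamples, " scored predictions spanning both ",
         "quality regimes")
  br <- seq(min(score), max(score), length.out = bins + 1L)
  h <- graphics::hist(score, breaks = br, plot = FALSE)$counts
  k <- gaussianKernel1d(smoothSigma)
  hs <- convolve1d(matrix(h, ncol = 1), k, along = 1L)[, 1]
  # local maxima of the smoothed histogram; a second mode only counts if a
  # genuine dip (below half the smaller mode) separates it from the main one
  isMax <- which(diff(sign(diff(c(-Inf, hs, -Inf)))) == -2)
  unimodalError <- function() {
    stop(structure(class = c("calibrationImpossible", "error", "condition"),
                   list(message = paste("quality distribution is unimodal;",
                                        "cannot locate a transition valley"),
                        call = sys.call())))
  }
  if (length(isMax) < 2) unimodalError()
  m1 <- isMax[which.max(hs[isMax])]
  # second mode: tallest local max well separated from the first and with
  # a genuine dip between them (sub-bumps of one mode do not qualify)
  cands <- isMax[order(hs[isMax], decreasing = TRUE)][-1]
  cands <- cands[abs(cands - m1) >= max(3L, bins %/% 8L)]
  m2 <- NA_integer_
  for (cand in cands) {
    between <- hs[min(m1, cand):max(m1, cand)]
    if (min(between) < 0.5 * min(hs[m1], hs[cand])) { m2 <- cand; break }
  }
  if (is.na(m2)) unimodalError()
  lo <- min(m1, m2); hi <- max(m1, m2)
  seg <- hs[lo:hi]
  # center of the minimum plateau between the two modes
  valleyBin <- lo + as.integer(round(mean(which(seg == min(seg))))) - 1L
  centers <- (br[-1] + br[-length(br)]) / 2
  halfBin <- (br[2] - br[1]) / 2
  sel <- abs(score - centers[valleyBin]) <= halfBin
  if (!any(sel)) {
    # empty valley: take the boundary sample of each quality regime
    below <- score < centers[valleyBin]
    sel <- seq_along(score) %in% c(
      which(below)[which.max(score[below])],
      which(!below)[which.min(score[!below])])
  }
  mean(U[sel])
}
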