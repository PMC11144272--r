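#' @import methods
NULL

#' Specification of a synthetic EM phantom
#'
#' Describes a deterministic synthetic electron-micrograph phantom:
#' elliptical organelles with internal cristae-like lamellae, curvilinear
#' membranes and a low-frequency background texture. The same spec always
#' produces the bit-identical image or volume.
#'
#' @slot height,width,depth image dimensions in pixels (`depth` is used only
#'   by [generatePhantomVolume()]).
#' @slot nOrganelles number of elliptical organelles to draw.
#' @slot membraneThickness membrane stroke width in pixels.
#' @slot textureScale correlation length of the background texture in pixels;
#'   `Inf` yields a flat background.
#' @slot intensityRange numeric length-2 vector, the output intensity range
#'   within \[0, 1\].
#' @slot seed integer RNG seed; part of the specification.
#'
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    height = "numeric", width = "numeric", depth = "numeric",
    nOrganelles = "numeric", membraneThickness = "numeric",
    textureScale = "numeric", intensityRange = "numeric", seed = "numeric"
  ),
  prototype(
    height = 128, width = 128, depth = 32, nOrganelles = 6,
    membraneThickness = 2, textureScale = 24,
    intensityRange = c(0.05, 0.95), seed = 1
  ),
  validity = function(object) {
    msg <- NULL
    if (object@nOrganelles < 0) msg <- c(msg, "nOrganelles must be >= 0")
    if (object@membraneThickness <= 0) msg <- c(msg, "membraneThickness must be > 0")
    if (object@textureScale <= 0) msg <- c(msg, "textureScale must be > 0")
    ir <- object@intensityRange
    if (length(ir) != 2 || any(ir < 0) || any(ir > 1) || ir[1] >= ir[2])
      msg <- c(msg, "intensityRange must be increasing within [0, 1]")
    if (is.null(msg)) TRUE else msg
  }
)

#' @describeIn PhantomSpec-class Constructor.
#' @param height,width,depth,nOrganelles,membraneThickness,textureScale,intensityRange,seed
#'   see slots.
#' @export
PhantomSpec <- function(height = 128, width = 128, depth = 32, nOrganelles = 6,
                        membraneThickness = 2, textureScale = 24,
                        intensityRange = c(0.05, 0.95), seed = 1) {
  new("PhantomSpec",
    height = height, width = width, depth = depth,
    nOrganelles = nOrganelles, membraneThickness = membraneThickness,
    textureScale = textureScale, intensityRange = intensityRange, seed = seed
  )
}

#' Dwell-time dependent detector noise model
#'
#' Poisson-Gaussian acquisition noise whose variance scales inversely with
#' the dwell time: a pixel with clean intensity \eqn{c} is observed as
#' \eqn{\mathrm{Pois}(g d c)/(g d) + \mathcal{N}(0, \sigma_r^2 / d)} where
#' \eqn{g} is the shot gain (electrons per intensity unit), \eqn{d} the dwell
#' and \eqn{\sigma_r} the read noise. Longer dwell means cleaner images, the
#' standard detector behaviour emulating acquisitions at different speeds.
#'
#' @slot dwell dwell time in arbitrary units; larger is cleaner.
#' @slot shotGain electrons per intensity unit per unit dwell.
#' @slot readSigma read-noise standard deviation at unit dwell.
#' @slot seed integer RNG seed.
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(dwell = "numeric", shotGain = "numeric",
                 readSigma = "numeric", seed = "numeric"),
  prototype(dwell = 1, shotGain = 60, readSigma = 0.05, seed = 1),
  validity = function(object) {
    msg <- NULL
    if (object@shotGain <= 0) msg <- c(msg, "shotGain must be > 0")
    if (object@readSigma < 0) msg <- c(msg, "readSigma must be >= 0")
    if (is.null(msg)) TRUE else msg
  }
)

#' @describeIn NoiseModel-class Constructor.
#' @param dwell,shotGain,readSigma,seed see slots.
#' @export
NoiseModel <- function(dwell = 1, shotGain = 60, readSigma = 0.05, seed = 1) {
  new("NoiseModel", dwell = dwell, shotGain = shotGain,
      readSigma = readSigma, seed = seed)
}

#' Acquisition drift model
#'
#' Stage drift and distortion between paired acquisitions: a global
#' homography composed with a smooth random displacement field, mirroring the
#' coarse (global) and fine (local) misalignments that two-stage registration
#' corrects.
#'
#' @slot homography invertible 3x3 matrix mapping target to source pixel
#'   coordinates (x, y, 1).
#' @slot smoothFieldAmplitude maximum displacement magnitude of the random
#'   field in pixels (>= 0).
#' @slot smoothFieldScale correlation length of the field in pixels.
#' @slot seed integer RNG seed.
#' @exportClass DriftModel
setClass("DriftModel",
  representation(homography = "matrix", smoothFieldAmplitude = "numeric",
                 smoothFieldScale = "numeric", seed = "numeric"),
  prototype(homography = diag(3), smoothFieldAmplitude = 0,
            smoothFieldScale = 32, seed = 1),
  validity = function(object) {
    msg <- NULL
    H <- object@homography
    if (!all(dim(H) == c(3, 3))) msg <- c(msg, "homography must be 3x3")
    else if (abs(det(H)) < 1e-12) msg <- c(msg, "homography must be invertible")
    if (object@smoothFieldAmplitude < 0)
      msg <- c(msg, "smoothFieldAmplitude must be >= 0")
    if (object@smoothFieldScale <= 0)
      msg <- c(msg, "smoothFieldScale must be > 0")
    if (is.null(msg)) TRUE else msg
  }
)

#' @describeIn DriftModel-class Constructor.
#' @param homography,smoothFieldAmplitude,smoothFieldScale,seed see slots.
#' @export
DriftModel <- function(homography = diag(3), smoothFieldAmplitude = 0,
                       smoothFieldScale = 32, seed = 1) {
  new("DriftModel", homography = homography,
      smoothFieldAmplitude = smoothFieldAmplitude,
      smoothFieldScale = smoothFieldScale, seed = seed)
}

#' Diffusion noise schedule
#'
#' The constants of the forward Gaussian diffusion: per-step noise rates
#' \eqn{\beta_t}, retention factors \eqn{\alpha_t = 1 - \beta_t}, their
#' cumulative products \eqn{\bar\alpha_t}, and the reverse-step noise scale
#' \eqn{\Sigma_t = (1 - \alpha_t) I} (stored as `sigma2`).
#'
#' @slot Tsteps number of diffusion timesteps.
#' @slot beta,alpha,alphaBar,sigma2 numeric vectors of length `Tsteps`.
#' @exportClass NoiseSchedule
setClass("NoiseSchedule",
  representation(Tsteps = "integer", beta = "numeric", alpha = "numeric",
                 alphaBar = "numeric", sigma2 = "numeric"),
  validity = function(object) {
    msg <- NULL
    Tn <- object@Tsteps
    if (length(object@beta) != Tn) msg <- c(msg, "beta must have length Tsteps")
    if (any(object@beta <= 0) || any(object@beta >= 1))
      msg <- c(msg, "all beta must lie in (0, 1)")
    if (any(diff(object@alphaBar) >= 0))
      msg <- c(msg, "alphaBar must be strictly decreasing")
    if (is.null(msg)) TRUE else msg
  }
)

#' Patch tiling grid
#'
#' Origins of fixed-size patches tiling an image, strided with a final
#' origin snapped flush to the far edge so that no pixels are lost. Origins
#' are zero-based (row, col) offsets, sorted row-major.
#'
#' @slot patchSize patch side length in pixels.
#' @slot stride stride between patch origins in pixels.
#' @slot origins integer matrix, one zero-based (row, col) origin per row.
#' @slot sourceShape integer length-2, (rows, cols) of the tiled image.
#' @exportClass PatchGrid
setClass("PatchGrid",
  representation(patchSize = "integer", stride = "integer",
                 origins = "matrix", sourceShape = "integer"),
  validity = function(object) {
    msg <- NULL
    o <- object@origins
    if (ncol(o) != 2) msg <- c(msg, "origins must have two columns")
    if (any(o < 0)) msg <- c(msg, "origins must be non-negative")
    if (any(o[, 1] + object@patchSize > object@sourceShape[1]) ||
        any(o[, 2] + object@patchSize > object@sourceShape[2]))
      msg <- c(msg, "every patch must lie fully inside the source")
    if (is.null(msg)) TRUE else msg
  }
)

#' Result of one registration stage
#'
#' @slot homography 3x3 matrix (identity for the fine stage).
#' @slot flowField numeric array height x width x 2 of per-pixel (dy, dx)
#'   displacements, or a zero-length array when the stage estimated none.
#' @slot warped the input image resampled onto the reference frame.
#' @slot nMatches number of inlier keypoint matches (coarse stage).
#' @slot residual mean reprojection error in pixels (coarse stage) or mean
#'   residual flow magnitude (fine stage).
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(homography = "matrix", flowField = "array",
                 warped = "matrix", nMatches = "integer",
                 residual = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@residual < 0) msg <- c(msg, "residual must be >= 0")
    if (object@nMatches > 0 && object@nMatches < 4)
      msg <- c(msg, "nMatches must be >= 4 when a homography was estimated")
    if (is.null(msg)) TRUE else msg
  }
)

#' Ensemble of diffusion restorations
#'
#' K independently sampled restorations of one input, their per-pixel mean
#' (the final prediction) and per-pixel standard deviation (the epistemic
#' uncertainty map, computed with denominator K - 1; all-zero when K = 1).
#'
#' @slot samples numeric array height x width x K.
#' @slot mean,std numeric matrices of the sample mean and SD.
#' @slot K number of samples.
#' @exportClass PredictionEnsemble
setClass("PredictionEnsemble",
  representation(samples = "array", mean = "matrix", std = "matrix",
                 K = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!all(dim(object@mean) == dim(object@samples)[1:2]))
      msg <- c(msg, "mean shape must equal sample shape")
    if (!all(dim(object@std) == dim(object@samples)[1:2]))
      msg <- c(msg, "std shape must equal sample shape")
    if (any(object@std < 0)) msg <- c(msg, "std must be >= 0")
    if (dim(object@samples)[3] != object@K)
      msg <- c(msg, "K must equal the number of samples")
    if (is.null(msg)) TRUE else msg
  }
)

#' Per-patch reliability report
#'
#' One uncertainty value per patch (the `q`-th percentile of the patch's
#' uncertainty map after per-patch min-max normalization of the underlying
#' samples), reliability flags at threshold `tau`, and the whole-image flag
#' (raised iff any patch is flagged).
#'
#' @slot patchValues numeric vector of per-patch uncertainty values U >= 0.
#' @slot tau reliability threshold (default 0.12).
#' @slot percentile the percentile used (default 99).
#' @slot patchFlags logical vector, `TRUE` where U > tau (unreliable).
#' @slot imageFlag `TRUE` iff any patch is flagged.
#' @slot origins zero-based patch origins, as in [PatchGrid-class].
#' @exportClass UncertaintyReport
setClass("UncertaintyReport",
  representation(patchValues = "numeric", tau = "numeric",
                 percentile = "numeric", patchFlags = "logical",
                 imageFlag = "logical", origins = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (any(object@patchValues < 0)) msg <- c(msg, "U must be >= 0")
    if (!identical(object@imageFlag, any(object@patchFlags)))
      msg <- c(msg, "imageFlag must be the OR of patchFlags")
    if (is.null(msg)) TRUE else msg
  }
)

#' A 3D grayscale EM volume
#'
#' Stack indexed (z, y, x) (zero-based layer arithmetic is confined to the
#' user-facing equations; storage is ordinary 1-based R indexing) with voxel
#' sizes in nm. The interpolation count R between adjacent axial layers is
#' derived from the voxel anisotropy as `round(z_nm / x_nm) - 1`.
#'
#' @slot data numeric array dim (z, y, x) with intensities in \[0, 1\].
#' @slot voxelSize numeric length-3 (z, y, x) voxel edge lengths in nm.
#' @exportClass EMVolume
setClass("EMVolume",
  representation(data = "array", voxelSize = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3) msg <- c(msg, "data must be 3D")
    else if (any(dim(object@data) < 2)) msg <- c(msg, "all dims must be >= 2")
    if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be three positive numbers (z, y, x)")
    if (is.null(msg)) TRUE else msg
  }
)

#' @describeIn EMVolume-class Constructor.
#' @param data 3D array (z, y, x).
#' @param voxelSize numeric length-3 (z, y, x) in nm.
#' @export
EMVolume <- function(data, voxelSize = c(1, 1, 1)) {
  new("EMVolume", data = data, voxelSize = as.numeric(voxelSize))
}
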