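#' Accessors for EMVolume
#'
#' @param object an [EMVolume-class].
#' @return `volumeData` returns the (z, y, x) array, `voxelSize` the numeric
#'   length-3 voxel edge lengths in nm, `nLayers` the number of axial layers,
#'   `interpolationCount` the derived per-gap interpolation count
#'   `round(z_nm / x_nm) - 1`.
#' @name EMVolume-accessors
NULL

#' @rdname EMVolume-accessors
#' @export
setGeneric("volumeData", function(object) standardGeneric("volumeData"))

#' @rdname EMVolume-accessors
#' @export
setMethod("volumeData", "EMVolume", function(object) object@data)

#' @rdname EMVolume-accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname EMVolume-accessors
#' @export
setMethod("voxelSize", "EMVolume", function(object) object@voxelSize)

#' @rdname EMVolume-accessors
#' @export
setGeneric("nLayers", function(object) standardGeneric("nLayers"))

#' @rdname EMVolume-accessors
#' @export
setMethod("nLayers", "EMVolume", function(object) dim(object@data)[1])

#' @rdname EMVolume-accessors
#' @export
setGeneric("interpolationCount",
           function(object) standardGeneric("interpolationCount"))

#' @rdname EMVolume-accessors
#' @export
setMethod("interpolationCount", "EMVolume", function(object) {
  vs <- object@voxelSize
  max(0L, as.integer(round(vs[1] / vs[3])) - 1L)
})

#' Patch grid accessors
#'
#' @param object a [PatchGrid-class].
#' @return `patchOrigins` returns the zero-based (row, col) origin matrix;
#'   `nPatches` the number of patches.
#' @name PatchGrid-accessors
NULL

#' @rdname PatchGrid-accessors
#' @export
setGeneric("patchOrigins", function(object) standardGeneric("patchOrigins"))

#' @rdname PatchGrid-accessors
#' @export
setMethod("patchOrigins", "PatchGrid", function(object) object@origins)

#' @rdname PatchGrid-accessors
#' @export
setGeneric("nPatches", function(object) standardGeneric("nPatches"))

#' @rdname PatchGrid-accessors
#' @export
setMethod("nPatches", "PatchGrid", function(object) nrow(object@origins))

#' Uncertainty report accessors
#'
#' @param object an [UncertaintyReport-class].
#' @return `patchValues` the per-patch uncertainty values; `isReliable`
#'   `TRUE` when no patch exceeded the threshold.
#' @name UncertaintyReport-accessors
NULL

#' @rdname UncertaintyReport-accessors
#' @export
setGeneric("patchValues", function(object) standardGeneric("patchValues"))

#' @rdname UncertaintyReport-accessors
#' @export
setMethod("patchValues", "UncertaintyReport", function(object) object@patchValues)

#' @rdname UncertaintyReport-accessors
#' @export
setGeneric("isReliable", function(object) standardGeneric("isReliable"))

#' @rdname UncertaintyReport-accessors
#' @export
setMethod("isReliable", "UncertaintyReport", function(object) !object@imageFlag)

#' Ensemble accessors
#'
#' @param object a [PredictionEnsemble-class].
#' @return `ensembleMean` the final prediction (per-pixel mean over K
#'   samples); `ensembleStd` the per-pixel SD.
#' @name PredictionEnsemble-accessors
NULL

#' @rdname PredictionEnsemble-accessors
#' @export
setGeneric("ensembleMean", function(object) standardGeneric("ensembleMean"))

#' @rdname PredictionEnsemble-accessors
#' @export
setMethod("ensembleMean", "PredictionEnsemble", function(object) object@mean)

#' @rdname PredictionEnsemble-accessors
#' @export
setGeneric("ensembleStd", function(object) standardGeneric("ensembleStd"))

#' @rdname PredictionEnsemble-accessors
#' @export
setMethod("ensembleStd", "PredictionEnsemble", function(object) object@std)

setMethod("show", "EMVolume", function(object) {
  d <- dim(object@data)
  vs <- object@voxelSize
  cat(sprintf("EMVolume: %d x %d x %d (z, y, x), voxel %g x %g x %g nm, R = %d\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3],
              interpolationCount(object)))
})

setMethod("show", "NoiseSchedule", function(object) {
  cat(sprintf("NoiseSchedule: T = %d, beta in [%.2g, %.2g], alphaBar[T] = %.3g\n",
              object@Tsteps, min(object@beta), max(object@beta),
              object@alphaBar[object@Tsteps]))
})

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf("PatchGrid: %d patches of %d px, stride %d, source %d x %d\n",
              nrow(object@origins), object@patchSize, object@stride,
              object@sourceShape[1], object@sourceShape[2]))
})

setMethod("show", "UncertaintyReport", function(object) {
  cat(sprintf(
    "UncertaintyReport: %d patches, tau = %.3g, %d flagged, image %s\n",
    length(object@patchValues), object@tau, sum(object@patchFlags),
    if (object@imageFlag) "UNRELIABLE" else "reliable"))
})

setMethod("show", "PredictionEnsemble", function(object) {
  cat(sprintf("PredictionEnsemble: K = %d samples of %d x %d, max SD %.4g\n",
              object@K, nrow(object@mean), ncol(object@mean),
              max(object@std)))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult: %d matches, residual %.3g px\n",
              object@nMatches, object@residual))
})
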