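#' emrestore: diffusion-based restoration for electron microscopy
#'
#' Conditional denoising diffusion models for EM micrograph denoising,
#' super-resolution and isotropic reconstruction of anisotropic volume-EM
#' stacks, with ensemble-based per-pixel uncertainty self-assessment,
#' coarse-to-fine registration of drifted acquisition pairs, synthetic EM
#' phantom generators and evaluation metrics.
#'
#' @keywords internal
#' @importFrom stats fft rnorm runif rpois quantile sd var
#' @importFrom utils read.table write.table
"_PACKAGE"
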