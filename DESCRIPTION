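Package: emrestore
Title: Conditional Diffusion Restoration and Isotropic Reconstruction for
    Electron Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Restoration of electron microscopy (EM) micrographs and volume-EM
    stacks with conditional denoising diffusion models. Implements denoising of
    short-dwell acquisitions, super-resolution of low-magnification scans, and
    isotropic reconstruction of anisotropic volumes by generating intermediate
    axial layers, each with ensemble-based per-pixel uncertainty
    self-assessment. Includes coarse-to-fine registration of drifted
    acquisition pairs, patch tiling and feathered stitching, a difficulty-aware
    heteroscedastic training objective, synthetic EM phantom generators for
    fully reproducible testing, and evaluation metrics (FSIM, Fourier ring
    correlation, spectral resolution estimation, IoU).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-image.R'
    'synthetic-em.R'
    'registration.R'
    'network.R'
    'diffusion-engine.R'
    'restoration2d.R'
    'uncertainty.R'
    'vem-iso.R'
    'metrics.R'
    'io.R'
    'cli.R'
    'zzz.R'
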