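# emrestore

Conditional-diffusion restoration for electron microscopy (EM) in R:
denoising of short-dwell micrographs, super-resolution of low-magnification
scans, and isotropic reconstruction of anisotropic volume-EM stacks, each
with ensemble-based per-pixel uncertainty self-assessment.

## The problem and who this is for

EM trades image quality against beam time: mapping nanoscale ultrastructure
at an adequate signal-to-noise ratio means long per-pixel dwell times and
therefore small imaged areas, and isotropic 3D (volume EM) acquisition is
restricted to specialised instruments and small volumes. For microscopists
and image-analysis developers, this package restores fast, degraded
acquisitions computationally and — because denoising, super-resolution and
axial interpolation are ill-posed — tells the user *where* its restorations
can be trusted.

## The model

A conditional denoising diffusion model underlies all tasks. A forward
process destroys a clean patch over *T* steps,
x_t = sqrt(ᾱ_t)·x₀ + sqrt(1−ᾱ_t)·ε with ᾱ_t = ∏(1−β_i), and a two-head
U-shaped network is trained to predict the injected noise ε given the
degraded acquisition as conditioning, under a difficulty-aware objective

    L = (1/N) Σ_i [ |ε − ε_θ|²_i / (2 φ_i²) + log φ_i ]

whose learned per-pixel difficulty map φ (minimised at φ* = |ε − ε_θ|)
down-weights pixels too noisy to explain. Restoration runs the process in
reverse from pure noise, guided by the input; each input is restored K = 2
times from independent seeds, the mean is the prediction, and the per-pixel
standard deviation δ of the draws is the epistemic uncertainty. A patch is
flagged unreliable when the 99th percentile of its (min-max normalised) δ
exceeds τ = 0.12, and one flagged patch flags the whole image.

For volumes, a sinusoidal *channel embedding* of the target layer index
j ∈ [1, R] lets one network generate all R missing layers between adjacent
anisotropic sections (R = axial/lateral voxel ratio − 1, e.g. 48 nm/8 nm
→ R = 5); training pairs layers R+1 apart along z of an isotropic volume,
or along y of the anisotropic volume itself when no isotropic data exists.

Supporting stages — coarse-to-fine registration of drifted acquisition
pairs (keypoint homography + dense optical flow), 256/196 patch tiling,
feathered stitching, FSIM / Fourier ring correlation / spectral resolution
/ IoU metrics, and fully synthetic EM phantom generators with known ground
truth — are all part of the package. See the methods vignette
(`vignettes/emrestore-methods.Rmd`) for the full account.

## Worked example

Simulate a paired acquisition (reference at 18x the raw dwell), train a
small denoiser, restore and self-assess:

```r
library(emrestore)

schedule <- buildSchedule(Tsteps = 50, betaMin = 0.004, betaMax = 0.35)
scenes <- simulateDenoisePairs(n = 100, side = 64, dwell = 1, seed = 1)
dataset <- lapply(scenes, function(p)
  list(x0 = 2 * p$clean - 1, cond = array(2 * p$raw - 1, c(64, 64, 1))))

net <- makeNetwork(condChannels = 1, baseWidth = 12, embDim = 16, seed = 1)
fit <- trainDiffusion(net, dataset, schedule,
                      trainConfig(learningRate = 3e-3, batchSize = 8,
                                  maxEpochs = 35, patience = Inf, seed = 1))

test <- simulateDenoisePairs(n = 1, side = 64, dwell = 1, seed = 999)[[1]]
out <- restoreImage(test$raw, fit$net, schedule, mode = "denoise",
                    K = 2, patchSize = 64, stride = 64, seed = 7)

cat(sprintf("FSIM noisy   vs clean: %.3f\n", fsim(test$raw, test$clean)))
cat(sprintf("FSIM restored vs clean: %.3f\n", fsim(out$image, test$clean)))
print(out$report)
```

Output from this exact script (roughly ten minutes on one CPU):

```
FSIM noisy   vs clean: 0.669
FSIM restored vs clean: 0.742
UncertaintyReport: 1 patches, tau = 0.12, 0 flagged, image reliable
```

The restored image scores markedly higher feature similarity against the
ground truth than the raw short-dwell scan, and the uncertainty value of
the single 64 px patch stays below the reliability threshold: the ensemble
draws agree. With noisier inputs (lower dwell), the report's patch values
rise and eventually flag the output — that is the self-assessment working,
not a failure mode.

For volumes, the same pattern:

```r
iso  <- generatePhantomVolume(PhantomSpec(height = 48, width = 48,
                                          depth = 31, seed = 101))
anis <- downsampleAxial(iso, 6)           # 8 nm -> 48 nm axial
samples <- buildTrainingSamplesI(iso, R = 5)
# ... train a 2-condition-channel network with useChannelEmbed = TRUE,
# then: inferIsotropic(anis, net, schedule, R = 5, K = 2)
```

A command-line wrapper with `simulate`, `register`, `train`, `finetune`,
`denoise`, `super-resolve`, `isotropize`, `assess` and `metrics`
subcommands is installed at `inst/cli/emrestore` (see `cliMain()`).

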