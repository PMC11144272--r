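---
title: "Diffusion-based EM restoration: models, parameters and design notes"
author: "emrestore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-based EM restoration: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Electron microscopy trades image quality against acquisition time: a
sufficient signal-to-noise ratio demands long per-pixel dwell times, which
caps the area that can be imaged, and isotropic volume EM demands
specialised instruments that cap the attainable volume. This package
restores fast, degraded acquisitions computationally: it denoises
short-dwell micrographs, super-resolves low-magnification scans, and
reconstructs isotropic volumes from anisotropic stacks by generating the
missing intermediate layers — in every case with a per-pixel self-assessment
of how much the result can be trusted.

# The model

## Conditional denoising diffusion

All three tasks share one generative core. A forward process gradually
destroys a clean patch $x_0$ (intensities mapped to $[-1,1]$) over $T$
steps,

$$x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon,
\qquad \epsilon \sim \mathcal N(0, I),$$

where $\bar\alpha_t = \prod_{i\le t}(1-\beta_i)$ and $\beta_1 < \dots <
\beta_T$ is the noise schedule (`buildSchedule()`). A network
$\epsilon_\theta(x_t, t, c)$ is trained to predict the injected noise given
the degraded acquisition $c$ as conditioning. Restoration runs the process
backwards from pure noise $x_T \sim \mathcal N(0, I)$:

$$x_{t-1} = \frac{1}{\sqrt{\alpha_t}}\Big(x_t -
\frac{1-\alpha_t}{\sqrt{1-\bar\alpha_t}}\,\epsilon_\theta(x_t,t,c)\Big)
+ \eta,\qquad \eta \sim \mathcal N(0, (1-\alpha_t) I),$$

with a deterministic final step ($\eta = 0$ at $t=1$) so the output is a
usable point estimate rather than a noisy draw. Because the sampler draws
*one plausible solution* of the ill-posed inverse problem rather than a
posterior mean, its outputs keep high-frequency detail that regression
models average away.

## Difficulty-aware objective

Extremely noisy patches produce outlier gradients that destabilise
training. The loss therefore carries a learned per-pixel difficulty map
$\varphi_i > 0$ (a second network head):

$$L = \frac1N\sum_i\left(
\frac{|\epsilon - \epsilon_\theta|^2_i}{2\varphi_i^2} + \log\varphi_i
\right).$$

The per-pixel minimiser is $\varphi^*_i = |\epsilon-\epsilon_\theta|_i$, so
$\varphi$ tracks the residual magnitude and down-weights pixels the model
cannot yet (or can never) explain; with $\varphi \equiv 1$ the loss reduces
to half the ordinary MSE. A useful side effect at small $T$: because
$\varphi$ renormalises the residual scale per pixel, every timestep
contributes comparably to learning even though the raw $\epsilon$-residual
varies with $t$ by orders of magnitude.

## Network and the residual parameterisation

The backbone (`makeNetwork()`) is a small U-shaped encoder–bottleneck–
decoder with skip connections, SiLU activations, a sinusoidal timestep
embedding added channel-wise in every block, and two $1\times1$ heads. The
difficulty head emits $\log\varphi$, clamped to $[-10, 10]$ before
exponentiation, so positivity is structural. Parameters are partitioned
into named groups — encoder, bottleneck, decoder, heads — which is what
makes selective fine-tuning verifiable (`parameterGroups()`).

The noise head is parameterised *through the clean image*: the network
predicts a correction $u$ to an analytic base restoration $b$ (the
condition itself for denoising and super-resolution; the $j$-weighted
linear blend of the two flanking layers for volumetric interpolation), and

$$\hat x_0 = \mathrm{clip}(b + u, -1, 1), \qquad
\epsilon_\theta = \frac{x_t - \sqrt{\bar\alpha_t}\,\hat x_0}
{\sqrt{1-\bar\alpha_t}}.$$

The two forms are algebraically interchangeable; the residual form is the
package's design choice because it concentrates the training budget where
it matters. At initialisation the full reverse sampler reproduces $b$
exactly, so a partially trained model degrades gracefully toward its input
instead of toward noise — the decisive property at the network sizes and
step counts a CPU can afford.

## Ensembling and self-assessment

Each input is restored $K$ times from independent noise seeds
(`predictEnsemble()`; $K = 2$ by default, following the published
recipe). The per-pixel mean of the $K$ draws is the final prediction; their
standard deviation $\delta_i$ (denominator $K-1$) is the epistemic
uncertainty — where independent draws from the learned solution
distribution disagree, the restoration is not trustworthy.

Uncertainty is scored patchwise (`assessImage()`): the $K$ samples of each
$256\times256$ patch are min-max normalised (making the score invariant to
affine intensity rescaling), $\delta$ is computed, and the patch value $U$
is the 99th percentile of $\delta$ — the top 1% of pixels are deliberately
ignored because isolated outliers and high-contrast structural boundaries
(organelle membranes) inflate $\delta$ without indicating a wrong
prediction. A patch with $U > \tau$ is flagged, and one flagged patch flags
the whole image. The default $\tau = 0.12$ is the published calibration of
this procedure against perceptual quality scores on a multi-noise-level
mouse cortex dataset; `calibrateThreshold()` implements the recalibration
path (histogram the quality scores, locate the valley between the two
modes, average the $U$ of the boundary samples) for users with their own
scored predictions.

# Task pipelines

**Denoising.** Training pairs are built from short-dwell raw scans
registered onto long-dwell references. Registration is coarse-to-fine
(`coarseAlign()`, `fineAlign()`): corner keypoints with oriented binary
descriptors are matched under a 0.75 ratio test and a RANSAC homography
(3 px inlier threshold) removes the global stage drift; polynomial-
expansion dense optical flow over a 3-level pyramid removes the residual
local distortion. Both stages are composed into a single bicubic
resampling of the raw image so interpolation loss is paid once. Aligned
images are tiled into $256\times256$ patches at stride 196, with the last
patch of each row/column snapped flush to the border so no pixels are
discarded (`cropPatches()`).

**Super-resolution.** The low-resolution patch is first rescaled
bicubically to the target geometry ($128\times128 \to 256\times256$ for a
$2\times$ pixel-size ratio, `prepareSRInput()`); the pipeline is otherwise
identical, with the rescaled image as conditioning.

**Isotropic reconstruction.** An anisotropic stack with axial/lateral
voxel ratio $R+1$ (e.g. 48 nm / 8 nm, $R = 5$) is completed by generating
the $R$ missing layers between every adjacent pair $(c^u, c^{u+1})$, each
draw conditioned on the pair plus a sinusoidal *channel embedding* of the
target index $j \in [1, R]$ (`channelEmbed()`), so one network serves all
intermediate positions. Training samples pair layers $R+1$ apart with the
layers between them as targets: along z of an isotropic training volume
(`buildTrainingSamplesI()`), or — when no isotropic data exists — along
the y axis of the anisotropic volume itself (`buildTrainingSamplesA()`),
exploiting that lateral cross-sections of cellular ultrastructure are
statistically exchangeable with axial ones. The y-axis variant sees
slices carrying the line artifacts of the anisotropic stack and overfits
to them if trained too long; its epoch cap defaults to 1200
(`vemATrainConfig()`). Inference (`inferIsotropic()`) interleaves
generated and original layers, giving $M + (M-1)R$ output layers, divides
the axial voxel size by $R+1$, and reports per-layer uncertainty. The
classical comparison point is per-column cubic interpolation along z
(`cubicBaseline()`).

**Restoring full frames.** `restoreImage()` ties the 2D pieces together:
tile, ensemble-sample per patch, stitch the means with linear feathering
weights normalised to sum to one at every pixel (exact in non-overlap
regions, convex in overlaps), and attach the uncertainty report.

# Parameters that matter

| Parameter | Default | Meaning / why |
|---|---|---|
| `T` (timesteps) | 1000 | production schedule; configurable down to ~50 for desk-scale runs |
| `betaMin`, `betaMax` | 1e-4, 0.02 | linear ramp; drives $\bar\alpha_T < 0.01$ so $x_T$ is noise-dominated |
| learning rate | 5e-5 | published training recipe (Adam, constant) |
| batch size | 64 | published training recipe |
| patience | 20 epochs | published early-stopping rule on validation loss |
| fine-tune lr / epochs | 1e-5 / 200 | published transfer-learning recipe; encoder frozen |
| `K` | 2 | published ensemble size; larger K smooths and costs resolution |
| `tau` | 0.12 | published reliability threshold; recalibrate per dataset |
| percentile `q` | 99 | outlier rejection in the patch uncertainty value |
| patch / stride | 256 / 196 | published tiling geometry |
| SR scale | 2 | 6.6 nm to 3.3 nm pixel-size ratio |
| axial factor | 6 | 8 nm to 48 nm mod-6 layer retention; $R = 5$ |
| vEM-a epoch cap | 1200 | overfitting guard for y-axis training |

When `T` is reduced for desk-scale runs the ramp must steepen so the
terminal state stays noise-dominated; the test suite uses `T = 50` with
$\beta \in [0.004, 0.35]$, giving $\bar\alpha_T \approx 4\times10^{-5}$,
matching the production default. Toy runs also raise the learning rate
(to ~3e-3) because at a few hundred optimisation steps the published 5e-5
would barely move the weights; the defaults remain the published values.

# The synthetic phantom generators

Every test and the acceptance study run on synthetic EM phantoms
(`generatePhantom2D()`, `generatePhantomVolume()`): elliptical organelles
bounded by dark membranes with internal cristae-like lamellae, curvilinear
membrane strands, and low-frequency background texture; volumes contain
membrane-bounded tubes whose centres and radii drift smoothly along z.
Acquisition noise is Poisson–Gaussian with dwell-scaled variance
(`applyNoise()`): $\mathrm{Pois}(g\,d\,c)/(g\,d) + \mathcal N(0,
\sigma_r^2/d)$, so the noise SD falls as $d^{-1/2}$ — the standard
detector model; the published work states only that pairs were acquired at
different times, so the law is this package's choice. The default
paired-acquisition preset uses a reference dwell 18 times the raw dwell,
the acquisition-speedup regime denoising targets. Stage drift is a global
homography composed with a bounded smooth random displacement field
(`applyDrift()`), mirroring the coarse/fine split of the registration
stages, and the true transforms are returned for oracle tests.

What the phantoms deliberately reproduce: sharp membrane edges closer
than the noise correlation length (the structures the paper argues
regression models smear), dwell-dependent noise, axially drifting sharp
structures (the regime where intensity-space axial interpolation ghosts
and learned interpolation can win). What they do not reproduce: realistic
EM texture statistics, charging/curtaining artifacts, detector
nonlinearities, or anything about a specific instrument. Passing the
package's tests therefore demonstrates that the algorithms are implemented
correctly and behave as designed under a controlled generative model — not
that a model trained on phantoms transfers to real micrographs; real use
requires training on real pairs.

# Numerical choices and degenerate inputs

* Images live in $[0,1]$; the diffusion core sees $[-1,1]$; volumes are
  normalised per volume, not per slice, so adjacent generated layers share
  one scale.
* Percentiles interpolate linearly between order statistics; min-max
  normalisation maps flat patches to all-zero rather than dividing by 0.
* The final reverse step adds no noise (the printed update rule adds
  $\mathcal N(0,\Sigma_t)$ at every step; a noiseless last step is needed
  for a point estimate and is recorded as a deliberate deviation).
* $K = 1$ yields a defined all-zero uncertainty map in
  `predictEnsemble()`, but `assessImage()` refuses $K < 2$: a reliability
  claim from one sample would be vacuous.
* Resampling is bicubic (Keys kernel, $a=-0.5$) with clamped borders;
  warp compositions (drift simulation, two-stage alignment) are collapsed
  into a single resampling pass to pay interpolation loss once.
* The patch grid snaps its last origin flush to the far edge; stitching
  weights are strictly positive feathering ramps normalised pixel-wise.
* Registration refuses inputs with fewer than 8 geometrically consistent
  matches (4 is the algebraic minimum for a homography; the stricter
  floor rejects coincidental agreement between unrelated images, and the
  failure carries the match count).
* The spectral resolution estimate uses a knee rule — the last frequency
  ring whose decorrelation gain is at least 10% of the largest gain —
  rather than a curve peak: the peak criterion of noise-based
  decorrelation analysis is undefined on noise-free synthetic images.
* FSIM uses the published constants ($T_1 = 0.85$, $T_2 = 160$ on a 0–255
  scale, four log-Gabor scales and orientations) with no retuning.

# Design decisions that were genuinely open

* **Noise-head parameterisation.** Discussed above; chosen for graceful
  degradation at desk scale. The loss, sampler and heads contract are
  unchanged.
* **Adaptive K.** The published noise-adaptive choice of $K$ relies on a
  pretrained no-reference quality model, which this package deliberately
  excludes; `chooseK()` exposes a variance-of-Laplacian proxy with a
  monotone step map defaulting to $K = 2$ as the documented substitute.
* **Edge policy for tiling.** The final snapped patch keeps every pixel at
  the cost of heavier overlap near borders; discarding remainders would
  silently crop images that are not multiples of the stride.
* **Fine alignment granularity.** Dense flow is estimated on full frames
  (pyramidal), not per tile: the displacement fields involved are smooth
  at the tile scale, and full-frame estimation avoids seam artifacts.
* **Image-level uncertainty.** Both the per-patch values and the flag
  union are stored; the image flag is the OR of patch flags so one bad
  patch is never averaged away.
* **HDF5.** Volume I/O is multi-page TIFF with a JSON sidecar for voxel
  sizes; no HDF5 binding is a package dependency.

# Problem sizes used in the shipped studies

The test suite and the acceptance script exercise the full pipelines at
sizes a single CPU handles in minutes: $T = 50$ diffusion steps,
$64\times64$ phantom patches (around a hundred training scenes for the
denoiser), $48\times48$ phantom volumes (training depth 67, test depth
31) with mod-6 axial downsampling, networks of base width 8–12, and
$K = 2$ ensembles. The axial-interpolation studies train the z-axis
variant for 40 epochs at rate 5e-4 and the y-axis variant for 12 epochs
at the same rate — the tighter cap is the desk-scale analogue of that
variant's production epoch cap, needed because cross-view training
overfits the view statistics long before the backbone converges. These
sizes are the package's choice of a reproducible reference experiment;
the pipelines themselves are size-agnostic.

# Known limitations

* The backbone is intentionally small; production-quality restoration of
  real EM data needs a larger network, $T \approx 1000$, GPU training, and
  real paired data.
* Training runs single-threaded on CPU; there is no GPU path.
* The uncertainty is the ensemble spread of one model — epistemic in the
  sampling sense, not a calibrated posterior; aleatoric/epistemic
  decomposition via model ensembles is out of scope.
* At desk scale the sampler is under-dispersed: the spread between K
  draws is dominated by reverse-chain noise passing through the
  network's state sensitivity, which concentrates at sharp membrane
  edges, rather than by genuine posterior ambiguity in noise-dominated
  regions. Reliability flagging (U against tau) works as designed, but
  the *growth* of U with input noise level — a property of
  production-scale models whose sample diversity reflects real solution
  ambiguity — is not reproduced by the toy models the test suite trains,
  and the corresponding check is expected to fail there.
* The registration stack assumes a single global homography plus smooth
  local flow; it will not handle piecewise or diffeomorphic deformations.
* `calibrateThreshold()` needs scored predictions spanning both quality
  regimes and refuses unimodal inputs rather than guessing.
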