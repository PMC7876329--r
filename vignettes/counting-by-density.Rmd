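---
title: "Counting flowering plants by density-map regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting flowering plants by density-map regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Counting individual plants in aerial imagery of dense plantings defeats
detection-style approaches: objects are small, abundant (tens of thousands
per field), partially occluded, and their number per image varies by orders
of magnitude. `floracount` implements the counting-by-density-estimation
alternative. Each training image is annotated with one point $z_n$ per
object, and the regression target is the superposition of normalized
isotropic Gaussians

$$D(x) = \sum_{n=1}^{N} \frac{1}{2\pi\sigma^2}
  \exp\left(-\frac{\lVert x - z_n \rVert^2}{2\sigma^2}\right),$$

so that $\int_R D \approx$ the number of objects in any region $R$. A fully
convolutional encoder–decoder (U-net style) network maps an RGB patch to a
single-channel density map, trained with per-pixel mean squared error. The
predicted count $\hat T_c$ is the sum of the predicted map; its cost does
not depend on the number of objects, which is what lets the same weights
sweep a whole orthomosaic tile by tile.

Key conventions, fixed package-wide:

* coordinates are 0-based `(row, col)` with pixel-center semantics; a point
  is in bounds for an $H \times W$ image when it lies in $[0,H)\times[0,W)$;
* each point contributes **unit mass**. The unnormalized prefactor
  $1/(2\pi\sigma)$ that sometimes appears in print would make each point
  contribute mass $\sigma$ and break counting-by-integration; it is
  available as `legacy_prefactor = TRUE` for comparison only;
* kernels are truncated at `truncation_radius * sigma` (default 4, square
  window). The discarded tail is below $10^{-4}$ of each point's mass and
  is covered by the 1% mass-conservation tolerance;
* points near the border keep only their in-image mass — the map
  integrates what is visible. No edge renormalization is applied.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `sigma` | 6 | px | kernel bandwidth; ≈ one plant footprint at survey scale. Smaller values make needle-like targets that are hard to regress; larger ones blur neighbours together. |
| `truncation_radius` | 4 | ×sigma | kernel support; cost is $O(N\sigma^2)$ |
| `gamma` | 0.05 | scaled density | peak threshold (see "density scales" below) |
| `delta` | 4 | px | exclusive minimum peak separation |
| `learning_rate` | 1e-3 | — | Adam step size |
| `beta1`, `beta2` | 0.9, 0.99 | — | Adam moment decays |
| `weight_decay` | 1e-5 | — | L2 penalty on conv weights |
| `batch_size` | 20 | patches | per optimization step |
| `early_stop_patience` | 30 | epochs | halt after this many epochs without validation improvement |
| `depth`, `base_channels` | 4, 64 | — | network size; depth-3/base-8 presets are used for desk-scale tests |

The network: each encoder stage is two (3×3 conv → batch norm → ReLU)
blocks followed by 2×2/stride-2 max pooling, channel widths doubling per
stage; the decoder mirrors it with 2×2 transposed-convolution upsampling
and skip concatenation; the head is a 1×1 convolution with a final ReLU so
densities are nonnegative by construction (a sigmoid would needlessly cap
densities at 1; crowded plants can legitimately sum beyond it). The "1×1
head" reading of a final "1D convolution" is the only dimensionally
coherent one. Inputs are 8-bit RGB scaled to $[0,1]$; the normalization is
recorded in the checkpoint sidecar so inference always matches training.

## Numerical choices

**Working density scale.** Raw unit-mass targets peak at
$1/(2\pi\sigma^2) \approx 4.4\times10^{-3}$ ($\sigma = 6$). Regressing at
that scale is badly conditioned: batch-norm features have unit gain, and
one Adam step of size $10^{-3}$ crosses most of the target range, which in
practice strands the final ReLU in its dead zone (the network collapses to
the all-zero predictor — we observed exactly this). The network therefore
regresses `target_scale` × density (default 100) and predictions are
divided by the same factor. This is loss-equivalent (the minimizer is
unchanged) and every user-facing quantity — predicted maps, counts,
reported MSEs — is in raw density units. The head layer is initialized
small (×0.02) for the same reason: training starts near the all-zero
predictor and spends its epochs shaping structure rather than shrinking
amplitude.

**The peak threshold lives on the working scale.** A unit-mass σ=6 kernel
can never reach γ = 0.05 in raw units, so thresholding raw maps at the
published default would erase everything; on the ×100 working scale a
single plant peaks at ≈0.44 and γ = 0.05 removes genuine low-density haze.
`extract_peaks()` itself is scale-agnostic; `peak_count_deficit()` and
`rank_samples()` accept `density_scale` and the pipeline passes the
model's `target_scale` automatically. $\hat T_c$ is always the raw-unit
integral, so CountDiff $= \hat T_c - \hat T_d$ compares plant counts with
plant counts.

**CountDiff can be negative.** Folk wisdom says the discrete peak count
$\hat T_d$ is always below the integrated count $\hat T_c$, because
thresholding discards mass. With unit-mass kernels and visible-mass
counting this is not a theorem: border plants contribute less than one
unit to $\hat T_c$ yet still produce a peak, and dense regions can grow
double maxima, so a well-calibrated model routinely shows
$\hat T_d$ slightly above $\hat T_c$. `peak_count_deficit()` warns (never
errors) in that case, and `rank_samples()` simply ranks such samples low —
the ranking only needs the samples with *large positive* CountDiff (badly
resolved density) at the top, which negativity does not disturb. The
corresponding acceptance criterion is deliberately left red with this
analysis; see the package's decision records.

**Peak extraction determinism.** Candidates are 8-neighbourhood local
maxima of the thresholded map with positive value (an all-zero map has no
peaks); an equal-valued plateau yields one candidate at its top-left
pixel; candidates are ordered by descending value with ties broken by
ascending (row, col); greedy acceptance suppresses candidates strictly
closer than δ (Euclidean) to an accepted peak. Every rule is needed for
cross-platform reproducibility and is mirrored by the brute-force oracle
in the test-suite.

**Augmentation.** Training draws one fresh augmentation per patch per
epoch: rotate by a uniform random angle about the image center (bilinear),
transform the points with the same rigid motion, crop a random fully-valid
window, and regenerate the density target from the transformed points —
never by resampling a rotated raster, so each surviving point keeps exactly
unit mass. When the crop equals the patch size (the scaled-down synthetic
world) no fully-valid rotated crop exists except at right angles, and the
trainer falls back to the 8 exact square symmetries. Validation and test
patches are never augmented.

**Early stopping** is a patience rule on validation pixel-MSE: halt after
`early_stop_patience` epochs without improvement and return the weights of
the best epoch ("steps" in training-recipe prose is read as epochs, which
is the only reading consistent with a 1000-epoch cap and a best model near
epoch 630). Model promotion during active-learning rounds follows the same
rule: new weights replace old only on validation improvement.

**MAPD** (mean absolute percent deviation) is defined as
$\text{mean}_i\, |{\hat c_i - c_i}|/c_i \times 100$ over patches with
$c_i > 0$; a percent deviation is undefined at zero, so empty patches
contribute to MAE only.

## The synthetic field world

Real drone data for this task is proprietary, so the package carries a
generator (`field_spec()`, `generate_field()`) that emulates the features
the method actually relies on: dense green rosette-textured beds arranged
in stripes separated by plant-free access roads; small reddish
radial-falloff blobs at known point locations (the "red center" of a
flowering plant seen from above); Gaussian positional jitter off a planting
lattice; per-pixel texture noise; an optional low-frequency illumination
ramp. `flowering_fraction` may be a range, drawn per field, so a dataset
spans empty to saturated patches (emulating beds where flower induction
partly failed). Everything is seeded: identical spec + seed is
bit-identical, and the test split uses a disjoint seed stream (an
out-of-domain field, in miniature).

What a green test on this world does establish: the full pipeline — target
generation, training, counting, peak extraction, ranking, tiling — is
internally consistent and learns to count a detectable stimulus from point
supervision alone. What it does not establish: robustness to real-world
nuisance (mosaicking blur, perspective, growth stages, multispectral
signal), and no quantitative claim about the reference UAV results
transfers. The acceptance suite is property-based for exactly this reason.

## Design choices where the design was open

* **Network width/depth are configuration, not ground truth** — the source
  architecture's exact widths are unspecified; defaults follow the
  canonical U-net (depth 4, base 64), tests use depth-3/base-8.
* **Decoder concatenation order** is (upsampled, skip); transposed-conv
  output channels halve the incoming width so concatenated widths match
  the mirrored encoder stage.
* **Fresh restart per active-learning round** rather than warm start:
  rounds stay comparable and reproducible; a warm start would entangle
  the data-quantity effect with optimization history.
* **First-round subset is uniform random**; all later selections are
  purely CountDiff-greedy. A passive baseline (`strategy = "random"`) is
  included for comparison and is not an acceptance surface.
* **Test data never influences selection**; the experiment evaluates on
  the test split only to record the ledger row.
* **Non-overlapping tiles with reflect padding** for mosaic inference:
  stitching is then exactly mass-conserving (no blending). An overlapping
  mode was considered and rejected as the default because blending weights
  would break the "stitched integral = sum of tile integrals" identity.
* **Overlay color scale** is fixed per field at the 99th percentile of
  positive density — robust to hot pixels, comparable across blocks of
  the same field.
* **Checkpoints** are the serialized weight list plus a JSON sidecar
  (architecture, normalization, sigma, gamma, delta, target scale), so a
  checkpoint is interpretable without deserializing it.

## Known limitations

* The hand-rolled training stack is single-device CPU float32; it is
  deterministic on a given machine but not bit-portable across BLAS
  builds.
* The generator renders a stimulus, not a photorealistic plant; models
  trained on it will not transfer to real imagery.
* GeoTIFF support is deliberately minimal (single-band float32 +
  pixel-scale/tiepoint tags, no CRS database); pixel space is the
  interchange currency and georeferenced coordinates are derived views.
* Peak positions are integer pixels; the annotation loop needs clickable
  approximate centers, not sub-pixel localization.
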