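---
title: "Multitask imaging-based cognition prediction: models, phantom and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask imaging-based cognition prediction: models, phantom and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`voxcog` predicts tissue segmentation, AD vs non-AD diagnosis, baseline
ADAS-Cog11 and its future exponential trajectory from one 3D structural
volume plus demographics. This vignette documents the modelling choices,
the synthetic phantom that stands in for restricted clinical cohorts, the
numerical decisions, and what the package's tests do and do not establish.

## The measurement model and the Gamma-prior loss

The cognition loss treats the observed score as a noisy measurement of the
latent cognitive state, `y_emp = y_true + eps`, `eps ~ N(0, sigma^2)`, and
places a right-skewed prior `p(y) ∝ (y/gamma) exp(-y/gamma)` on the score
itself (a Gamma density with shape 2 and scale `gamma`; ADAS-Cog11
marginals are strongly right-skewed). The negative log posterior, dropping
its normalisation constant, is

```
L(y) = (y - y_emp)^2 / (2 sigma^2) - log(y / gamma) + y / gamma.
```

Because the constant is dropped, only differences and minimisers of this
loss are meaningful; its value can be negative. Predictions must be
positive: the network head uses a softplus link and the boosting objective
optimises in log space (`y = e^f`), with the analytic gradient
`y (y - y_emp) / sigma^2 - 1 + y / gamma` and Hessian
`(2 y^2 - y_emp y) / sigma^2 + y / gamma`.

**Parameters.**

* `gamma` (score points) is estimated per training fold as `mean(y) / 2`,
  the maximum-likelihood estimate under the shape-2 density (its mean is
  `2 gamma`). Fold-local estimation is part of the leakage discipline: the
  parameters of the loss never see validation or test labels.
* `sigma` (score points) is, in the model above, the *measurement error of
  the instrument* — not the population spread of scores. The package
  default is 3 points, the scale of ADAS-Cog's reported test-retest error
  (`adas_measurement_sd()`). The design was genuinely open here and we
  initially used the training-label standard deviation; with that choice
  `sigma ~ 7` and the prior overwhelms the likelihood, shrinking all
  predictions toward the prior mode and *hurting* out-of-fold R² relative
  to plain MSE, the opposite of the loss's purpose. With `sigma` at the
  measurement scale the Gamma objective consistently matches or beats MSE
  on the phantom (majority of paired replicates, mean CV-R² margin around
  +0.02). `sigma = "sd"` is retained as an explicit conservative option.
* The Hessian is floored at `1e-6` (it is genuinely negative for
  `y < y_emp / 2`); because a floored Hessian makes Newton leaf steps
  arbitrarily large, the boosting wrapper also caps per-leaf steps
  (`max_delta_step = 0.5`). This is a stability measure of the optimiser,
  not a change to the loss.

## Network architecture

A 3D UNet with two 3×3×3 convolutions (padding 1, each followed by ReLU)
and 2×2×2 max pooling per contracting block, a 128-channel bottleneck at a
fixed 4³ spatial size, and an expanding path of 2×2×2 up-convolutions with
skip concatenation, ending in a 1×1×1 convolution to 4 classes with a
per-voxel softmax. The bottleneck flattens to exactly 8,192 = 128·4³
features; demographics (7 one-hot/standardised inputs) are concatenated to
this vector and three fully connected layers (widths 256 and 64, then
per-task linear heads) produce the scalar outputs.

Open choices and how they were fixed:

* Channel progression 16→32→64(→128): the doubling convention with the
  128-channel endpoint forced by the stated bottleneck size.
* Demographics fusion: concatenation at the flattened bottleneck, before
  the first fully connected layer. ("Input layer" fusion is ambiguous for
  a convolutional encoder; bottleneck concatenation is the standard late
  fusion point.)
* No normalisation layers inside convolution blocks.
* The decline-rate head is trained against a standardised target
  (training-fold mean/sd), de-standardised at prediction time; the raw
  rates live at 1e-2/month and otherwise condition the shared trunk badly.
* Freeze policy: segmentation pretraining trains everything; the multitask
  phase freezes the expanding arm and final classifier (they serve only
  segmentation) and trains the contracting arm and fully connected layers.
* Backbone swap: any encoder–decoder exposing `(seg_probs, bottleneck)`
  can replace the UNet; the package's training loop only touches that
  surface. Pretrained transfer-learning backbones are out of scope.

There is no GPU framework underneath: convolutions are computed in single
precision as 27 offset GEMMs against shifted input copies (RcppArmadillo),
with max-pool argmax caching, a transposed-convolution kernel, and a C++
Adam update. Gradients were verified against central finite differences
kernel-by-kernel (exact in the linear regime) and end-to-end.

## Training schedule

Desk-scale defaults (one CPU): batch size 1, Adam at 0.001.

1. **Segmentation pretraining** (3 epochs): all layers, cross-entropy only,
   elastic augmentation at every step (one Gaussian-smoothed displacement
   field, smoothing sd 4 voxels, magnitude 1 voxel, applied trilinearly to
   the image and by nearest neighbour to the labels). A zero-atrophy
   young-control cohort can be pooled in to enlarge the sample.
2. **Head warm-up**: bottleneck features are extracted once and the fully
   connected layers are trained full-batch on the scalar losses
   (cognition-Gamma + decline rate + diagnosis), early-stopped on the
   validation multitask loss (checks every 10 iterations, patience 10,
   minimum 200 iterations so the slower heads get a budget; cap 600).
3. **Joint fine-tuning** (2 epochs, lr 2e-4): the full combined loss
   (weights 0.5 cognition, 0.5 segmentation, 0.25 rate, 0.25 diagnosis)
   through the contracting arm with the expanding arm frozen; the best
   validation state is kept, so a fine-tune that degrades validation loss
   is discarded.
4. **Ensemble retraining**: module CV R² values become normalised convex
   weights; the imaging loss is scaled by its R² weight (the tabular term
   does not flow gradients into the network), the tabular model is
   refitted, and segmentation has no ensemble.

Model selection uses validation folds only; the set-aside 10% test
partition is touched exactly once per study, at final evaluation.

## The phantom cohort

The generator produces, per subject: a three-tissue head (background
shell, CSF rim and ventricles, WM core, GM ribbon as radial bands of a
mildly anisotropic ellipsoid), a label map, an intensity volume (tissue
means 0.05/0.55/0.85/0.25 for background/GM/WM/CSF, partial-volume
Gaussian blur sd 0.6 voxel, additive noise sd 0.05), demographics, and
cognition. It emulates:

* **Severity.** A latent `s ~ Gamma(shape 2, scale 5)` drives everything;
  the baseline score is `ADAS_0 = clip(s + N(0, 2), 0, 70)`, so the ADAS
  marginal is Gamma-shaped (KS distance to the fitted shape-2 reference
  ≈ 0.03–0.04 at n = 5,000). Diagnosis bands: `s < 5` CN, `5 ≤ s < 15`
  MCI, `s ≥ 15` AD.
* **Atrophy.** Deterministic voxel removal makes GM strictly decreasing in
  `s`: a contiguous "hotspot" (the 15% of GM nearest a fixed off-centre
  focus, the analogue of hippocampal/temporal vulnerability) is eroded at
  a rate that consumes it fully at `s = 4·scale`, plus mild global
  outer-ribbon thinning (0.5% of GM per score point). Eroded voxels become
  CSF. The hotspot's voxel set and bounding box are recorded as ground
  truth for attribution tests.
* **Anatomical variability.** Disease subjects get sub-voxel centre
  shifts, head-size jitter (sd 2%), GM/CSF outer-boundary jitter (sd 0.02
  of the half-grid) and GM/WM inner-boundary jitter (sd 0.035). These were
  calibrated once so that the module hierarchy matches the published
  regimes the framework was designed for: demographics+volumes boosting
  reaches CV R² ≈ 0.2–0.3 (total volumes are a *noisy* severity readout —
  erosion-added CSF is confounded with sulcal and head-size variation),
  while the imaging model can read the focal hotspot pattern directly and
  reaches R² ≈ 0.6–0.7 on held-out subjects. Young controls have zero
  atrophy, no geometric jitter (so their GM count equals the template's
  exactly) and no cognition labels.
* **Demographics.** Age is rank-correlated with the latent severity
  (Gaussian copula, ρ = 0.45, leaving the severity marginal exactly
  Gamma), reflecting the age–severity coupling of dementia cohorts. This
  gives demographics a weak but real cognition signal, so the tabular
  module contributes information genuinely complementary to the imaging
  module — without it, R²-weighted ensembling could only dilute the
  imaging predictions. Sex, education and marital status are generated but
  carry no cognition signal by design (useful as known-null features in
  importance tests).
* **Decline.** `alpha_true = 0.005 + 0.01·(GM z-deficit vs CN) +
  0.002·(age − mean) + N(0, 0.005)` per month; follow-ups at months
  0, 6, 12, 18, 24, 36 follow `ADAS_0 · e^{alpha T}` with 5% multiplicative
  lognormal noise, clipped to the instrument range [0, 70]. Negative
  `alpha_true` occurs, so the improving-decliner filter has real work.

What the phantom deliberately lacks: MRI physics (bias fields, scanner
effects), real cortical geometry, site effects, and heteroscedastic or
non-Gaussian measurement error. Tests passing on the phantom therefore
establish that the *machinery* recovers the structure it assumes — not
that the framework attains any particular accuracy on clinical data.

## Longitudinal model

`alpha` is fitted per subject by least squares in log space through the
fixed baseline: `alpha = Σ T·(log(y_T + δ) − log(y_0 + δ)) / Σ T²` over
follow-up visits. The offset `δ = 1` handles zero scores (cohorts of
healthy adults reach ADAS 0); `δ = 0` is exposed for the raw-scale variant
(then the single-visit case reduces to `log(y_T / y_0) / T`, and the fit is
scale-equivariant). The baseline is pinned, not a free intercept, matching
the forecasting use: predictions are `(b + δ)e^{αT} − δ` from either the
empirical baseline (known-baseline mode) or the model's predicted baseline.
MCI/AD subjects with fitted `alpha < 0` are removed before longitudinal
evaluation (strict inequality; CN subjects are never removed). Per-visit
metrics require at least 3 subjects at a month; smaller months are reported
absent.

## Interpretability

* **Occlusion maps**: 5³ cubes at stride 5 ("occlusion unit of five
  voxels" read as a cube), scoring the increase in squared cognition error
  attributed to the patch's voxels; decreases are floored at zero. Cohort
  maps are scaled jointly so the global maximum is 10, then averaged. The
  function's default fill is 0 (the volume mean in normalised-intensity
  space), but for atrophy-driven predictions that fill is close to CSF and
  therefore nearly transparent exactly where tissue has already been lost;
  the AD mean-map protocol instead fills the cube with healthy-GM
  intensity taken from the model's own segmentation, probing the
  counterfactual "this region looks intact". On the phantom study the
  top-scoring voxels of that map concentrate in the generator's hotspot
  bounding box — the localization check has exact ground truth.
* **Permutation importance**: 25 iterations of single-column resampling,
  reporting the distribution of R² decreases.
* **Inclusion importance**: ΔR² between the ensemble and the tabular-only
  model on the same validation subjects.
* **Receptive-field summary**: n = 250 sampled (subject, position) channel
  vectors per layer, PCA to 3 components, k-means with k = 3, cognition
  tertiles attached, and bottleneck pseudolabels projected back to parent
  encoder positions.

## Numerical choices and degenerate inputs

* All voxelwise losses are voxel means, so the multitask weights are
  comparable across tasks of different output dimensionality.
* Cross-entropy probabilities are clamped at 1e-12 (with a warning when
  truth mass sits on a clamped voxel); the binary log loss clamps
  symmetrically.
* Dice with hard labels one-hot-encodes them, making the min-based soft
  overlap reduce to the classical intersection; class weights default to
  equal and per-class unweighted Dice is also reported.
* Constant volumes cannot be normalised (error); constant training targets
  yield a constant predictor with a warning; a constant tabular feature has
  exactly zero permutation importance.
* Split construction uses largest-remainder allocation of the test quota
  across diagnosis strata, then cycles fold labels, so a 100-subject cohort
  yields exactly 10 test subjects and nine folds of 10.
* Seeds: every stochastic stage (phantom, splits, shuffling, augmentation,
  boosting, permutation, sampling) takes an explicit seed and restores the
  caller's RNG state.

## Problem sizes

The package's own study — used by the test suite — is a 32³ phantom cohort
of 200 subjects (180 train across 9 folds, 20 set-aside test), 3
segmentation-pretraining epochs, ≤600 warm-up iterations and 2 fine-tuning
epochs, with the tabular comparison run on 10 labels-only cohorts of 500
subjects. On one CPU the full study trains in roughly ten minutes. The 64³
/ depth-4 configuration is exercised for its architecture contract
(bottleneck length, parameter count) rather than trained in the tests.

## Known limitations

* The phantom's geometry is radial-band anatomy; segmentation is far
  easier than real tissue segmentation, so Dice values are not comparable
  to clinical benchmarks.
* The Gamma-vs-MSE comparison measures a small consistent edge (~+0.02 CV
  R²) under additive homoscedastic measurement noise; mechanisms that
  plausibly amplify the benefit on real data (heteroscedastic operator
  noise, multiplicative error) are intentionally absent from the phantom.
* The multitask fine-tune keeps the best validation state; on easy phantom
  cohorts this often selects the warm-up state, i.e. the encoder is
  effectively frozen after pretraining.
* Diagnosis is binary (AD vs CN+MCI); three-way classification is out of
  scope.
* Inference-time ensembling uses normalised-R² convex averaging of module
  predictions; the ensemble loss proper is used for retraining only. The
  "ensemble loses at most a little against its best module" property is
  checked on the set-aside partition; on single 20-subject validation
  folds the tabular module's R² estimate is too unstable for it to hold
  uniformly.
* The tabular boosting defaults are conservative (shallow subsampled
  trees); a demographics-only model on the phantom stays weaker than its
  clinical analogue because most phantom demographics are null features by
  construction.
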