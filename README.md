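# voxcog

Multitask prediction of brain-tissue segmentation, diagnosis, baseline
cognition and future cognitive decline from a single 3D structural MRI
volume plus minimal demographics.

## The problem

Clinical assessment of Alzheimer's disease relies on cognitive batteries —
most importantly the ADAS-Cog11 score — that are slow, operator-sensitive
and burdensome. A model that reads one baseline T1-weighted scan together
with age, sex, education and marital status, and returns (i) a GM/WM/CSF
tissue segmentation, (ii) an AD vs non-AD diagnosis probability, (iii) the
current ADAS-Cog11 score and (iv) its future trajectory, offers a
non-invasive surrogate for that battery. `voxcog` implements such a
framework end-to-end for researchers in imaging-based dementia prognosis,
together with a synthetic brain-phantom cohort generator, so every stage is
testable without access to restricted clinical cohorts.

## The model

**Imaging module.** A 3D UNet: a contracting path of blocks with two
3×3×3 convolutions (padding 1, ReLU) and 2×2×2 max pooling, a 128-channel
bottleneck at 4³ spatial size, and an expanding path of 2×2×2
up-convolutions with skip connections ending in a 1×1×1 classifier over
{background, GM, WM, CSF}. The bottleneck is flattened into a feature
vector of length 8,192 = 128·4³, concatenated with the one-hot
demographics, and passed through three fully connected layers to scalar
heads: cognition (softplus link), decline rate α, and diagnosis (sigmoid).
There is no deep-learning framework underneath — the forward and backward
passes are implemented in the package (RcppArmadillo GEMM kernels).

**Gamma-prior cognition loss.** ADAS-Cog11 is nonnegative and
right-skewed; its marginal is well approximated by the density
p(y) ∝ (y/γ)·e^{−y/γ}. Combining this prior with a Gaussian measurement
model y_emp = y_true + ε, ε ~ N(0, σ²) gives the negative log posterior

    L_Γ(y) = (y − y_emp)² / (2σ²) − log(y/γ) + y/γ   (+ const),

used both for the network's cognition head and as a custom gradient
boosting objective (optimised in log space, y = e^f, with analytic gradient
and Hessian). γ is estimated per training fold as mean(y)/2 (the MLE of the
shape-2 density); σ is the instrument's measurement error (≈3 score points
for ADAS-Cog11), not the population spread.

**Multitask objective.** L = λ_Cog·L_Cog + λ_Seg·L_Seg + λ_α·L_α +
λ_Diag·L_Diag with λ_Cog = λ_Seg = 0.5 and λ_α = λ_Diag = 0.25.
Segmentation is pretrained first (optionally with a young-control cohort);
in the multitask phase the expanding arm is frozen.

**Ensemble.** A gradient-boosted tabular model (demographics + segmented
tissue volumes) is trained in parallel; module predictions are combined
with weights proportional to each module's cross-validated R², and the
imaging module is retrained under the ensemble loss
L = R²_Im·L_Im + R²_NIm·L_NIm.

**Longitudinal forecasting.** Each subject's trajectory is summarised by
the exponential rate α in ADAS_T = ADAS_0·e^{αT} (fitted in log space
through the fixed baseline, with an offset for zero scores); future
cognition is forecast from α and either the known or the predicted
baseline. MCI/AD subjects with improving fitted trajectories (α < 0) are
filtered out as operator noise.

**Interpretability.** Occlusion maps (5³ cubes, stride 5) of the cognition
head with cohort aggregation normalised to a global maximum of 10 and
atlas-wise averaging; permutation importance (25 iterations) and inclusion
importance (ΔR² with vs without imaging) for the tabular features; and a
receptive-field feature-manifold summary (PCA d=3, k-means k=3, n=250
samples).

## Worked example

```r
library(voxcog)

# R2-weighted ensemble: with published-scale module R2 values (imaging 0.72,
# tabular 0.31) the mixing weights split ~70/30
w <- compute_ensemble_weights(r2_im = 0.72, r2_nim = 0.31)
cat(sprintf("imaging weight  w_im  = %.3f\ntabular weight  w_nim = %.3f\n",
            w$w_im, w$w_nim))
#> imaging weight  w_im  = 0.699
#> tabular weight  w_nim = 0.301

# Gamma-prior loss: fold-local parameters and the closed form at the mode
gp <- estimate_gamma_params(c(4.1, 7.9, 12.4, 21.0, 9.6, 6.2))
cat(sprintf("gamma_hat = %.3f, sigma = %.1f\n", gp$gamma, gp$sigma))
#> gamma_hat = 5.100, sigma = 3.0
gamma_loss(gp$gamma, gp$gamma, gp)   # y = y_emp = gamma
#> [1] 1

# Exponential decline: fit a trajectory, forecast 36 months out
f <- fit_alpha(months = c(0, 6, 12, 24), adas = c(12, 13.1, 14.6, 18.2))
cat(sprintf("alpha_hat = %.5f per month\n", f$alpha))
#> alpha_hat = 0.01592 per month
forecast_adas(f$baseline_used, f$alpha, 36)
#> [1] 22.06847

# Phantom cohort: the baseline cognition marginal is Gamma-shaped
co <- generate_cohort(phantom_config(grid_size = 32, n_subjects = 400,
                                     seed = 7, make_images = FALSE))
gp2 <- estimate_gamma_params(co$records$adas0)
ks_distance_to_gamma(co$records$adas0, gp2$gamma)
#> [1] 0.0306478
```

The ensemble weights mean the tabular module contributes ~30% and the
imaging module ~70% of the combined cognition prediction; the Gamma loss
equals exactly 1 when the prediction sits at both the measurement and the
prior mode; the fitted α of ~0.016/month corresponds to a score rising from
12 to ~22 over three years; and the phantom's ADAS marginal is within KS
distance 0.03 of the shape-2 Gamma shape it is designed to follow.

A full pipeline (simulate → pretrain → train → evaluate → predict →
explain) is exposed as `cmd_*()` functions driven by a YAML config, plus a
thin command-line wrapper in `inst/cli/voxcog`.

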