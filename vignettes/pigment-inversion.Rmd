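---
title: "From leaf spectra to canopy pigment maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From leaf spectra to canopy pigment maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hsiPigments estimates foliar pigment content (Chl a, Chl b, carotenoids,
and their total, mg per g fresh mass) from Vis-NIR hyperspectral
reflectance, and projects leaf-trained models onto whole canopies pixel
by pixel. This vignette is the package's own account of the science:
the models, their assumptions, the tunable parameters, what the
synthetic generator does and does not emulate, and the numerical design
choices a maintainer would want written down.

## The measurement model

A push-broom Vis-NIR imager records raw counts per pixel and band.
Counts become reflectance through the standard two-point calibration
against a high-reflectance white plate and a shutter-closed dark frame,

$$R = \frac{R_{raw} - R_{dark}}{R_{white} - R_{dark}},$$

applied per band (`calibrateReflectance()`). The formula assumes a
linear sensor and spatially uniform illumination after correction;
bands where white ≤ dark have no valid gain and raise an error rather
than being clamped. References may be per-band vectors or full cubes
(reduced by spatial mean, the push-broom convention).

Canopy pixels are separated from background by thresholding a single
near-infrared band, 748.76 nm by default: vegetation reflects strongly
on the NIR plateau while soil and trays stay dark, so the grey-level
histogram is bimodal there. The threshold is chosen by Otsu's
between-class-variance criterion; when the histogram has an empty gap
between modes the criterion plateaus, and the cut is placed at the
plateau midpoint so it sits centrally in the gap. A fixed threshold can
be supplied for fixed-cut workflows, and the value used is always
recorded in the mask's provenance attribute.

Wet-lab ground truth comes from ethanol-extract spectrophotometry. With
background-corrected absorbances at 665, 649 and 470 nm, concentrations
are first computed in µg/mL (13.95·A665 − 6.88·A649 for Chl a;
24.96·A649 − 7.32·A665 for Chl b; (1000·A470 − 2.05·Ca − 114.8·Cb)/245
for carotenoids) and then scaled by V/(1000·W) to mg per g fresh mass.
Two readings of the carotenoid line are possible from its typography;
only the one implemented — the divisor 245 applying to the whole
numerator, with the chlorophyll terms still in µg/mL — is dimensionally
consistent, and it is the standard spectrophotometric form. Negative
components (possible with noisy absorbances) are flagged, never
truncated, so downstream statistics remain unbiased.

## The chemometric grid

Classical calibration in this field is a pipeline of interchangeable
stages, and which combination wins is an empirical question. The
package therefore exposes the full factorial grid
(`runGrid()`): preprocessing {none, MA, SNV, D1} × band selection
{CARS, SPA, LARS, UVE} × sample splitting {Random, KS, SPXY} ×
regressor {PLSR, RF, SVR, ELM}, per pigment — 192 combinations per
target when run in full.

Design rules that keep the grid honest:

* **Preprocessing is fit-free.** MA (default window 5 bands — narrow
  enough to keep 2.4 nm-sampled absorption troughs distinct), SNV
  (sample standard deviation, n−1, used consistently package-wide) and
  the first derivative (central differences over the wavelength axis,
  one-sided at the ends) learn nothing from the data, so they can be
  applied before splitting without leakage, and band indices keep their
  meaning across the grid.
* **Selection sees calibration rows only.** Permuting prediction-set
  targets changes neither the selected bands nor any calibration
  metric; this is asserted by a canary test. (KS and SPXY place
  *samples* using the full design — that is what those methods are.)
* **Determinism.** Every stochastic stage derives its own seed from the
  global seed and the combination label via a 32-bit FNV-1a hash, so a
  rerun reproduces every report; all ranking ties break toward the
  lower band index.

The selectors follow their standard formulations: CARS runs a
Monte-Carlo loop (default 50 iterations, 80 % row subsampling, 5-fold
cross-validated RMSE, PLS components ≤ 10 — values from the original
CARS literature, all configurable) with the retained-band count forced
down an exponential schedule calibrated so the first iteration keeps
everything and the last keeps 2 bands; SPA grows a minimal-collinearity
chain by successive orthogonal projections (with `"auto"` start, every
starting band is tried and chains are scored by the same PLS-CV
criterion as CARS); UVE appends uniform noise bands (magnitude
10⁻³·max|X|) and keeps real bands whose leave-one-out PLS coefficient
stability beats the 0.99 quantile of the noise bands'; LARS is the
Efron least-angle path on internally standardized columns, reported in
entry order. PLS itself is delegated to mixOmics (centering only, no
per-band scaling, the reflectance convention), with the component count
capped at the effective rank of the centred calibration matrix —
noise-free synthetic spectra are exactly low-rank and deeper components
are numerically meaningless.

Splitting defaults to 3:1 calibration:prediction (standard practice;
the ratio is a parameter). SPXY normalizes the spectral and response
distance matrices each by its own maximum before summing.

Regressor hyperparameters (RF 500 trees; RBF-SVR with C ∈ {1,10,100}
and γ ∈ 1/p·{0.1,1,10} by 5-fold CV on calibration statistics only;
ELM with 200 hidden sigmoid units, random ±1 weights on standardized
inputs and pseudoinverse output weights; PLSR components by 5-fold CV
up to 15) are defaults chosen from common practice and are all
configurable and logged.

## The deep regressor

The end-to-end model maps a raw 256-band spectrum to one pigment value
(one scalar model per pigment). Its stack: three 1-D convolution blocks
(kernel sizes 7/5/3, channels 16/32/64, stride 1, each followed by ReLU
and max-pool 2 — mixed kernel sizes capture features at several
spectral scales), a bidirectional LSTM over the pooled band sequence
(64 units per direction) to carry long-range band-to-band context, a
six-head self-attention block over the resulting tokens, mean pooling,
and a dense head. With width 128 and six heads the per-head dimension
is ⌊128/6⌋ = 21; the heads concatenate to 126 and the output projection
returns to width 128. Attention scores are scaled by 1/√d_k by default
(the standard stabilization); `scale_scores = FALSE` gives the literal
unscaled dot-product variant, and both are tested against an
independent step-by-step reference implementation. Attention rows are
asserted to sum to 1 on every forward pass.

Training: Adam (learning rate 10⁻³), batch size 32, mean-squared error,
200 epochs; inputs are standardized per band and the target z-scored
with calibration statistics only (stored in the model so prediction
works on raw spectra). Per-epoch calibration loss and prediction-set R²
are tracked, and the reported model is the epoch with the best
prediction R² (`select_best = FALSE` keeps the last epoch instead).
None of the optimizer settings are sacred; they are recorded in every
report.

No deep-learning framework is available to R in this environment, so
the forward and backward passes are implemented from first principles,
with the inner loops in RcppArmadillo. Correctness rests on two
supports: every analytic gradient is checked against central finite
differences through the full stack, and the fused C++ training step is
checked to agree with the modular per-layer path to 10⁻¹⁰ on all four
ablation variants (CNN, CNN-BiLSTM, CNN-MHSA, full model). The ablation
harness trains all four variants under identical seeds, split and
hyperparameters.

## The synthetic generator

Real lettuce cubes are not distributable with the package, so every
stage is validated against synthetic data whose ground truth is known
by construction. A leaf spectrum is a smooth base curve — visible
plateau 0.10, green reflectance peak at 550 nm, sigmoid red edge
centred at 720 nm rising to a NIR plateau near 0.55 — minus
pigment-weighted Gaussian absorption features (sd 18 nm) at the in vivo
centers: Chl a 430 and 680 nm, Chl b 450 and 650 nm, carotenoids
470 nm. The 680 nm center (rather than the 665 nm extract-assay
wavelength) is deliberate: in-leaf Chl a absorbs near 680, and it
places the mean-spectrum red trough inside the 670–690 nm window where
real leaf spectra show it. Pigments are drawn independently and
uniformly within the observed leaf ranges (Chl a 0.68–0.99, Chl b
0.29–0.45, Car 0.14–0.23 mg/g; TPC is their exact sum), additive
Gaussian noise defaults to 0.002 reflectance units (~0.5 % of the
visible signal), and reflectance is clipped to [0, 1.05] as calibrated
cubes can slightly overshoot the white reference.

In linear mode the pigment→spectrum map is exactly affine, so full-rank
regression on the informative bands recovers the targets to machine
precision — the base for all exactness tests. In nonlinear mode
absorption depth saturates Beer–Lambert-style as 1 − exp(−kc), with k
set so the top of each pigment's range reaches ~80 % of saturation —
enough curvature that linear and nonlinear regressors genuinely
separate. Canopy scenes place a disk of leaf spectra (pigments varying
affinely with relative radius, emulating centre-to-periphery trends) on
a flat 0.15-reflectance soil background, which gives > 0.3 reflectance
contrast on the NIR plateau.

The generator also reports its causally informative bands. Two
subtleties matter for selector validation, both diagnosed on this
benchmark. First, at 2.4 nm sampling the neighbours of an 18 nm-wide
absorption centre carry essentially the same signal, so no selector can
be expected to hit exact indices; recovery (`bandRecovery()`) counts a
truth band as found when a selected band lies within ±3 indices (~7 nm).
Second, supervised selectors see one target: when predicting Chl a, the
Chl b/carotenoid blue features add no information beyond what the
red-region pair already provides, and a correct selector drops them.
Recovery is therefore scored against the target pigment's own causal
centres (`truthBands(x, "chla")`), not the union over pigments.

What the generator does **not** emulate: radiative-transfer realism
(no PROSPECT-style leaf structure, no specular or illumination-geometry
effects, no sensor point-spread function), empirical correlations among
pigments (draws are independent), scattering baselines that SNV/MSC
exist to remove, and instrument artifacts such as spectral smile.
Passing tests therefore demonstrate algorithmic correctness and
recoverability under known physics — not field performance on real
canopies.

## Numerical choices and degenerate inputs

* Rank-capped PLS components (see above); univariate predictor matrices
  fall back to ordinary least squares.
* KS/SPXY ties (duplicate points, equal max-min distances) break toward
  the lower index; both methods are bitwise deterministic.
* SPXY guards both normalizations: constant y reduces it to KS,
  constant X leaves the response distance alone.
* SNV on a zero-variance spectrum and calibration with white ≤ dark are
  errors, not silent zeros; empty masks and all-sentinel maps are valid
  degenerate outputs (with a warning where ambiguity matters).
* The ELM pseudoinverse uses `MASS::ginv`, so exactly collinear hidden
  activations are handled; with ≥ n hidden units it interpolates its
  calibration data, a property used as a test oracle.
* ENVI I/O stores float32; a written cube re-reads bitwise identically
  after one quantization round trip, and all three interleaves are
  cross-checked against each other.

## Problem sizes used by the test suite

The validation suite runs entirely on synthetic data at sizes chosen to
keep a full run on one CPU comfortable while leaving the conclusions
meaningful: oracle checks at n ≤ 12 (splitters) and ≤ 8 tokens
(attention); selector-recovery studies at 100 samples × 256 bands × 10
seeds; the deep-model benchmark at 500 samples × 256 bands × 200
epochs; and the ablation study at 500 samples × 64 bands × 60 epochs
× 10 seeds with a reduced net (channels 8/16/32, 32 LSTM units), sizes
at which all four variants converge. The ablation conclusion is
directional — the full model's prediction R² beats the plain CNN's in
at least 8 of 10 seeds on the saturating benchmark — not a claim about
absolute accuracy on real data.

## Known limitations

Scope is the leaf-to-canopy inversion workflow itself: no geometric or
smile/keystone correction, no mosaicking, no stratified splitting by
cultivar, no Savitzky–Golay smoothing or MSC (the plain first
derivative and SNV are implemented; Savitzky–Golay would be a natural
extension), no GPU path, and no transfer of trained models across
instruments with different band grids (nearest-neighbour band matching
within the grid is the only tolerance). Canopy maps are strictly
pixelwise by design — no spatial regularization — which preserves vein
texture but also preserves pixel noise.
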