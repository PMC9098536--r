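---
title: "Models and methods behind gliomark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gliomark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomark)
```

# The scientific problem

Glioblastoma (GB) and a solitary brain metastasis (BM) are often
indistinguishable on conventional contrast-enhanced MRI, yet their
management differs radically. Three physiological axes separate them:

* **Peritumoral perfusion.** GB infiltrates beyond the enhancing rim, so
  relative cerebral blood volume (rCBV) is elevated in the edema within
  about 5 mm of the tumour; metastatic edema is purely vasogenic and, if
  anything, hypoperfused.
* **Capillary permeability.** GB vessels retain a largely functional
  blood–brain barrier, so the first-pass dynamic susceptibility contrast
  (DSC) signal recovers nearly to baseline (high percentage signal
  recovery, PSR). Metastatic capillaries are of systemic type and leak,
  depressing PSR.
* **Cellularity.** The solid GB component is hypercellular, restricting
  water diffusion (low ADC); metastases have looser, vascular stroma
  (higher ADC).

`gliomark` quantifies all three from a DSC time series, a multi-b DWI
stack and a set of region masks, and feeds the extracted per-case features
into a ROC-based statistical stage. Defaults throughout are parameterized
by the reported group statistics of a 41-patient reference cohort
(20 GB / 21 BM) scanned at 1.5 T with TR/TE 1490/40 ms, 50 dynamic frames
(at least five pre-bolus), and b = 0/500/1000 s/mm².

# Perfusion quantification

## Signal model and concentration

For a gradient-echo DSC acquisition the transverse relaxation change is
taken proportional to contrast concentration, and the package works in
ΔR2\* units (1/s) throughout:

$$\Delta R_2^*(t) = -\frac{1}{TE}\,\ln\frac{S(t)}{S_0},$$

with $S_0$ the mean of the pre-bolus baseline frames (`estimate_baseline`,
default 8 frames, never fewer than 5). The proportionality constant to
mmol/l is scanner-dependent and never needed: CBV is a ratio of integrals
and rCBV is additionally normalized to reference tissue, so the constant
cancels. Samples above baseline give negative ΔR2\* and are retained in
the curves; voxels with non-positive signal are marked invalid rather than
raising errors, because single corrupted voxels must not abort a map.

## Deconvolution

The tissue curve is modelled as
$C_t(t) = \mathrm{CBF}\cdot (C_a \circledast R)(t)\,\Delta t$ with residue
$R(t)$ the fraction of tracer still in tissue. `deconvolve_block_circulant_svd`
solves the discrete system on a zero-padded circulant matrix (padding to
the next power of two of twice the curve length), which makes the estimate
insensitive to bolus delay, and regularizes by zeroing singular values
below a fraction of the largest.

* `sv_threshold_fraction` (default **0.10**): the community-standard
  operating point for noisy in vivo data. Regularization should match the
  noise level: on noiseless simulations a threshold this aggressive
  truncates genuine high-frequency content of the residue and
  underestimates CBF substantially, while **0.005** recovers the residue
  essentially exactly. The package therefore keeps 0.10 as the clinical
  default and the verification suite passes an explicit 0.005 for
  noiseless forward–inverse consistency checks (200 random draws with
  CBF ∈ [0.2, 3] 1/s, MTT ∈ [2, 12] s at the default frame timing recover
  CBF within 5% in well over 95% of cases).
* CBF is read off as the maximum of the recovered flow-scaled residue,
  clipped at zero; no negative-lobe clipping is applied inside the linear
  solve, which would bias it.

## CBV, rCBV and PSR

`compute_cbv` integrates by the trapezoidal rule over the full window,
clipping negative ΔR2\* samples to zero first so blood volumes cannot go
negative. A numerical caveat documented here deliberately: with the
rectangle-rule discrete convolution above, the discrete residue "area"
is $\mathrm{MTT} + \Delta t/2$ rather than MTT, so the central volume
theorem $CBV = CBF \cdot MTT$ holds only to a relative error of about
$\Delta t/(2\,\mathrm{MTT})$ at the 1.49 s frame spacing (≈15% at
MTT = 5 s). This is a property of the forward model's quadrature, not an
implementation error; the test suite verifies the theorem on a finely
sampled curve (Δt = 0.2 s), where it holds within a few percent, and
verifies forward–inverse CBF consistency at the clinical timing, where
forward and inverse quadratures match exactly.

rCBV normalizes the CBV map by the mean over a contralateral
normal-appearing white matter mask, making the reference mean exactly 1.
"Corrected" rCBV here means this normalization only; contrast-leakage
correction of the rCBV integrand is intentionally out of scope.

PSR is computed **on the VOI-mean signal curve** (one curve per lesion,
then one summary), not voxel-wise and averaged — the study design this
emulates reports a single PSR per lesion:

$$\mathrm{PSR} = 100 - \frac{100\,(S_0 - S_\mathrm{end})}{S_0 - S_\mathrm{min}}$$

with $S_\mathrm{end}$ the mean of the last `end_window = 5` frames. If the
curve never drops more than twice the baseline standard deviation below
baseline, there is no detectable bolus: PSR is reported as 100 with a
`no_bolus` flag rather than an exception (0/0 at a flat curve).

# ADC mapping

Per voxel, ordinary least squares of $\ln S(b)$ on $b$; ADC is minus the
slope in mm²/s. Unweighted OLS matches how scanner consoles generate the
maps, and with only three b-values the difference from signal-weighted
fitting is negligible. The fit is exact on noiseless mono-exponential
signals (verified to 1e-9 relative) and invariant to intensity scaling.
ADC is kept in mm²/s internally; the ×10⁻³ presentation convention is
applied only in the CSV layer.

# VOI construction

Three study VOIs are built from input masks (automatic tumour
segmentation is out of scope; masks come from the phantom truth or a
user's segmentation):

1. **Solid lesion**: enhancing mask minus necrotic/cystic core
   (`lesion_voi`); an entirely necrotic "lesion" is an error.
2. **Perilesional ring**: all edema within `width_mm = 5` of the lesion
   (`perilesional_ring`). The 5 mm statement is physical, so dilation uses
   an exact Euclidean distance transform in millimetres (separable
   lower-envelope algorithm) that respects anisotropic voxel spacing —
   with 5 mm slices, voxel-count dilation would be wrong by a factor of
   five in the slice direction.
3. **Residual edema**: edema minus lesion minus ring (`residual_edema`);
   may legitimately be empty.

Two discretization choices deserve a note:

* **Surface correction.** A mask boundary samples the underlying
  continuum surface at voxel centres that sit, on average, about a
  quarter voxel inside it. Thresholding the centre-to-centre distance at
  exactly `width_mm` therefore under-covers the true 5 mm band, while
  measuring distance to the voxel *cubes* over-covers it (cube corners
  protrude past the surface). `perilesional_ring` adds a midpoint
  correction of `min(spacing)/4` to the threshold, which reproduces
  analytic shell volumes on sphere phantoms to within ~2% and converges
  with voxel size; `surface_correction_mm = 0` restores plain
  centre-based dilation.
* **Edema intersection.** Whether the 5 mm band should be restricted to
  FLAIR-hyperintense voxels is genuinely open; the default intersects
  with the edema mask (the band is drawn *in* edema), and
  `restrict_to_edema = FALSE` gives the freehand alternative.

Feature extraction (`extract_case_features`) projects the three VOIs on
the ADC and rCBV maps (grids must match exactly — co-registration is a
non-goal, replaced by a strict equality check) and records min/mean for
ADC, mean/max for rCBV, plus the lesion-curve PSR. Empty regions yield NA
features for that region while the rest of the record is computed.

# Statistical stage

* **Group comparison**: Welch's t test by default — the reference cohort's
  group SDs are far from equal (e.g. 0.64 vs 1.72 for perilesional rCBV
  max), which makes the equal-variance assumption untenable; the pooled
  variant is available.
* **ROC**: empirical curves over midpoints between adjacent distinct
  scores, AUC as the Mann–Whitney statistic with half credit for ties.
  The operating cutoff maximizes the Youden index J = sensitivity +
  specificity − 1 ("maximize both"), ties broken toward the pooled median
  score. `binormal_auc` provides the closed form
  $\Phi(|\Delta\mu|/\sqrt{\sigma_1^2+\sigma_2^2})$ used as an analytic
  oracle in the tests.
* **Combination**: "maximum-likelihood combination of classifiers" is
  implemented as its closest standard reading — a logistic-regression
  linear combiner on standardized features (the ML fit of the linear
  score), falling back to the LDA direction under perfect separation
  (where the logistic MLE diverges). Of the two perilesional rCBV
  statistics, the **max** (the thresholded quantity) enters the combined
  classifier; the mean is available as an option.
* **Decision rule**: GB ⇔ perilesional rCBV max > 1.37 ∧ PSR > 75% ∧
  lesion mean ADC < 1.0×10⁻³ mm²/s, strict inequalities, conjunctive by
  default (`any`/`majority` configurable); GB is the positive class
  everywhere. No multiple-testing correction is applied by default (raw
  p-values are reported); Bonferroni can be applied by the user.

# Synthetic data: what it emulates and what it does not

## Feature cohorts

`default_cohort_spec()` encodes per-group Gaussians for the four
discriminating features (lesion mean ADC, perilesional rCBV max and mean,
PSR) at the reference cohort's means/SDs with n = 20 GB / 21 BM. Because
only marginal group statistics are reported, features are sampled
**independently** by default; a Gaussian copula with a user-supplied
correlation matrix is available for sensitivity analysis. Consequences to
keep in mind:

* Single-feature quantities (AUCs, sensitivity/specificity at a fixed
  cutoff) depend only on the marginals and replicate closely.
* The combined-classifier AUC under independence has the analytic bound
  $\Phi(\sqrt{\sum_i a_i^2})$ with $a_i = |\Delta\mu_i|/\sqrt{\sigma_{1i}^2+\sigma_{2i}^2}$
  ≈ 93.3% for the three discriminators — close to, but not identical
  with, the value the real (correlated) cohort produced. Passing tests on
  synthetic cohorts therefore validates the machinery, not the clinical
  effect size of the combination.
* ADC draws are truncated at zero by redrawing (a physical constraint).
  For the GB lesion ADC (μ/σ ≈ 2.15) this shifts the sampled mean by
  ≈ 4% of σ, so the tests compare sampled moments against the analytic
  zero-truncated normal, not the untruncated one. PSR is *not* truncated
  at 100: overshoot is physical under T1-dominant leakage.

## Digital phantoms

`build_phantom` realizes a spherical concentric geometry (necrotic core ⊂
enhancing lesion ⊂ edema, default radii 4/10/20 mm on a 40³ grid at 2 mm
isotropic) plus an arterial sphere carrying the input function and a
contralateral white-matter reference sphere. Per region, the DSC signal is
generated by the forward model

$$S(t) = S_0\,\exp\!\big(-TE\,(C_t(t) + L(t))\big),$$

where $C_t$ is the CBF-scaled convolution of a gamma-variate bolus
(arrival at 10·TR, shape α = 3, β = 1.5 s — a typical first-pass shape
that fits comfortably inside the 50-frame window; peak arterial ΔR2\*
12 1/s, giving realistic 30–50% tissue signal drops) with an exponential
residue, and $L(t)$ is a smooth logistic post-bolus offset (centred on the
tissue bolus peak, time constant 2 s, zeroed before bolus arrival so
baseline frames stay exactly at $S_0$). $L$'s height is calibrated by root
finding so the noiseless curve's PSR equals the requested target —
the reference cohort reports only the *measured* PSR, not a leakage
mechanism, so the generator reproduces the measurement rather than
positing microvascular physics. DWI volumes are
$S_b = S_0 e^{-b\,\mathrm{ADC}}$. Noise is additive Gaussian on signal
magnitude — adequate at the simulated SNRs and with analytically
tractable error propagation; Rician bias, motion, ghosting, realistic
anatomy and multi-coil effects are deliberately not modelled, so phantom
tests validate numerics, not robustness to those artifacts.

Ground-truth rCBV per region is computed from the same noiseless forward
curves with the same integral definition the analysis uses. This makes
round-trip error measure the *pipeline* (noise handling, voxel averaging,
VOI construction) rather than quadrature mismatch; for regions with full
signal recovery the value coincides with CBF·MTT normalized to the
reference. `gb_phantom_spec()`/`bm_phantom_spec()` set region truths at
the respective group means (lesion ADC 0.71 vs 1.13 ×10⁻³ mm²/s, ring
rCBV 2.63 vs 1.21, PSR 84.59 vs 71.14%).

# Numerical and design choices, collected

* Random-number use is always locally seeded (`with_seed`) and restores
  the caller's RNG state; identical (spec, seed) pairs give bit-identical
  outputs.
* Forward convolution is computed directly (not via FFT) so pre-bolus
  samples are exactly zero.
* PSR calibration solves a strictly monotone 1-D root problem with
  `uniroot` to 1e-10; targets above 100 yield negative ramp heights.
* The distance transform is the exact separable lower-envelope algorithm
  with per-axis physical spacing; tested against brute force.
* Degenerate inputs are contracts, not crashes: empty lesion → error;
  empty ring/residual edema → warning + NA features; flat perfusion
  curve → `no_bolus` flag; all-constant t-test groups → t = 0, p = 1;
  perfect separation → LDA fallback with a warning.
* Problem sizes in the test and verification suites — 2×10⁵ cases per
  synthetic group for ROC quantities (empirical AUC within 0.01 of the
  binormal closed form), 200 deconvolution draws, 40³ phantoms at 2 mm,
  and a 64³ 1 mm grid for analytic shell-volume geometry — were chosen so
  Monte-Carlo error is far below the tolerances being asserted while the
  whole suite stays fast.

# Known limitations

* No arterial-input auto-selection, delay/dispersion correction, leakage
  (Boxerman-type) correction, or DCE permeability modelling.
* No image registration or resampling: all inputs must share one grid.
* Independence of synthetic features is an explicit approximation; the
  patient-level sensitivity/specificity of the *combined* rule depends on
  the real joint distribution and is not reproducible from marginal
  statistics.
* ΔR2\* is used as the concentration unit; absolute quantification in
  mmol/l is not attempted (and cancels from every reported quantity).
* IVIM, kurtosis, tensor metrics, texture and learned features are out of
  scope.
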