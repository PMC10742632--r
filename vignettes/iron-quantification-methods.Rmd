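---
title: "Methods: T2* relaxometry, cardiac mapping, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: T2* relaxometry, cardiac mapping, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferriscope)
```

`ferriscope` implements the quantitative chain used to assess transfusional
iron burden with MRI — decay-model relaxometry, the 16-segment cardiac map,
Simpson volumetry, threshold-based classification — and the cohort statistics
that link vitamin-D status to myocardial iron. This vignette documents the
models, the tunable parameters, the numerical choices, and what the synthetic
data do and do not emulate.

## Signal models

Multi-echo gradient-echo magnitude images decay mono-exponentially with echo
time in iron-loaded tissue. The package fits ROI-mean decay curves (the mean
magnitude under the ROI mask at each echo; pixel-wise mapping is out of
scope) with two models:

* **Constant-offset model**: `S(TE) = S0 exp(-TE / T2*) + C`, with `C >= 0`
  absorbing the noise-floor plateau of magnitude data. This is the default
  for liver, pancreas, and mildly loaded myocardium, using all echoes.
* **Truncation model**: `S(TE) = S0 exp(-TE / T2*)` after discarding late
  echoes with inadequate signal-to-noise. When a background noise estimate
  `noise_sd` is available, trailing echoes whose observed ROI-mean signal is
  below `2 * noise_sd` are removed; without one, trailing echoes are removed
  while removal improves the adjusted R². At least 3 echoes are always
  retained. This rule is an explicit stand-in: published truncation protocols
  exist in several variants and none is restated here in full.

Optimisation is Levenberg–Marquardt (`minpack.lm::nls.lm`) with relative
tolerances of 1e-10 on parameters, started from a log-linear regression on
the first half of the echoes with `C0 = min(signal)`. The parameters live in
a physical box (`T2* ∈ [0.2, 1e4]` ms, `S0 <= 1e4 × max signal`,
`C <= 2 × max signal`): on decays that sit in the noise floor beyond the
first echo or two, the unconstrained SSE surface is flat along
`T2* -> 0, S0 -> ∞`, and an unbounded optimizer diverges along it. Noiseless
model-generated decays are recovered to better than six significant digits
(asserted in the tests), and on noisy input the optimizer matches a dense
grid-search oracle within 1%.

**Model arbitration.** The offset model is fitted first; if it reports
`T2* < 10` ms — the conventional severe-cardiac-iron boundary, configurable
via `heavy_iron_t2star_threshold` — the decay is re-fitted with the
truncation model and that result is returned. An offset fit that fails to
converge is itself a symptom of a noise-floor decay and is routed to the
truncation model rather than raised.

**Echo grid.** The emulated protocol acquires 10 echoes with 2.26 ms
spacing. The first echo time is not separately specified by the protocol
description, so `default_echo_times()` starts at one spacing (2.26 ms);
everything is metadata-driven and other grids pass through unchanged.

**Liver iron.** LIC is derived from hepatic T2\* with a calibration linear
in R2\* = 1000/T2\* (Hz): `LIC = 0.0254 * R2* + 0.202` mg/g dry weight by
default. The coefficients are configurable and every result carries a
`calibration_id`, because multiple published calibrations are in clinical
use and results must say which produced them.

## Cardiac 16-segment mapping

Short-axis slices are partitioned per the AHA model: 6 equiangular sectors in
basal and mid slices, 4 in the apical slice, counterclockwise from a
reference angle. The angular origin (anatomically, the anterior RV insertion)
cannot be derived from contours alone, so it is an explicit input defaulting
to 90° (anterior). Myocardial pixels are those whose centres fall inside the
epicardial and outside the endocardial contour; sector assignment bins the
pixel-centre angle about the myocardial centroid, which makes the masks an
exact partition (tested property). Global heart T2\* is the arithmetic mean
of the 16 segmental values. A segment is "low" when its T2\* is at or below
20 ms: the clinical convention defines *normal* as strictly above 20 ms, so
exactly 20.0 ms counts as abnormal (this boundary is pinned by a test). The
per-segment susceptibility-correction hook multiplies fitted segmental T2\*
values and defaults to identity; published correction coefficients are not
reproduced.

## Ventricular function

Volumes use Simpson's rule as plain disc summation,
`V = Σ area_i × (thickness + gap)`, with no geometric model — 0.8 cm slices
and no gap by default. EF is `(EDV − ESV) × 100 / EDV` and LV mass is
myocardial volume × 1.05 g/cm³. The convention that papillary muscles belong
to the myocardium rather than the blood pool is a contract on the supplied
contour areas, not something the package can compute. BSA defaults to
Du Bois (`0.007184 h^0.725 w^0.425`) with Mosteller selectable; the source
protocol does not state its formula, so the default is the one most common
in cardiac MRI reference ranges.

## Diagnostic thresholds

All cut-offs live in one `iron_thresholds()` object (YAML round-trippable):
vitamin D deficient below 20 ng/mL, sufficient at or above 30 ng/mL (the US
Endocrine Society bands; serum 25(OH)D is handled in ng/mL throughout);
hepatic overload at LIC ≥ 3 mg/g dw; pancreatic overload strictly below
26 ms (26.0 itself is normal — "lower cut-off for normal" read as
inclusive); myocardial overload at heart T2\* ≤ 20 ms; PTH normal in
[4.4, 58.6] pg/mL inclusive.

## Cohort statistics

Group comparisons follow standard clinical-study practice: a
Lilliefors-corrected Kolmogorov–Smirnov check on within-group residuals
routes normal data to the t-test/ANOVA and non-normal data to
Mann–Whitney/Kruskal–Wallis; categorical variables go to χ². For unpaired
two-group data the rank test is Mann–Whitney (a signed-rank test requires
pairing that a cross-sectional cohort does not have). Pairwise post hoc
p-values are Bonferroni-multiplied and capped at 1.

2×2 odds ratios are the crude `(ad)/(bc)` with the Woolf log-scale interval
`exp(ln OR ± z √(1/a + 1/b + 1/c + 1/d))`, which for a single binary
predictor coincides with the logistic-regression Wald estimate (verified
against a logistic ML fit in the tests). Zero cells raise an error unless
the Haldane–Anscombe 0.5 correction is requested.

The stepwise model z-scores outcome and candidates (so betas are
standardized), screens candidates univariately at p < 0.05, then runs
forward selection with entry at p ≤ 0.05 and removal at p > 0.10 — the
common statistics-package convention; the source analysis does not state its
thresholds. Collinearity is summarised by VIF (flagged > 5) and tolerance
(flagged < 0.20) on the final model. Designs collinear to singularity error
with the offending variables named.

ROC analysis enumerates all observed thresholds; AUC is the Mann–Whitney
concordance (ties at half weight), the CI is DeLong's, and the operating
point maximises Youden's J with ties broken toward higher sensitivity.
`direction = "low"` covers predictors where low values predict the event —
a patient is called positive when vitamin D is at or below the cut-off.

## Synthetic data

**Phantoms.** `make_phantom()` renders uniform discs, a three-ROI pancreas,
a liver slab, or a three-slice 16-segment cardiac annulus at known
per-region T2\*, then corrupts every pixel with Rician noise (magnitude of a
complex Gaussian centred on the model signal — the noise law of magnitude
MRI; background pixels are Rayleigh with mean σ√(π/2), a tested closed
form). Phantom validation places no true segmental value exactly on the
20 ms threshold: a boundary-exact truth makes the low/normal call a coin
flip under any noise level.

**Cohort.** `generate_cohort()` emulates a 278-patient cohort in three
vitamin-D groups (75 sufficient / 96 insufficient / 107 deficient). Within
each group a latent Gaussian copula drives vitamin D, ferritin, LIC,
pancreatic and cardiac T2\*, and PTH; each margin is transformed to its
configured family — log-normal with exactly moment-matched parameters for
the right-skewed variables (ferritin, liver enzymes, LIC, pancreatic T2\*,
whose reported SDs approach or exceed half their means), truncated normal
for the rest. Vitamin D is truncated inside the group's category band, so
the three category counts match the group sizes exactly by construction.
Rank correlation is targeted rather than Pearson because Spearman's ρ is
invariant under the monotone marginal transforms.

Two calibrations deserve explanation:

* *Between-group inflation.* The reported correlations are whole-cohort
  values, but group means are themselves ordered (deficient patients have
  the lowest heart T2\*, the highest LIC, and so on), which adds a
  between-group component on top of the within-group copula. The generator
  therefore deflates the within-group latent correlations by a deterministic
  fixed-point iteration (internal fixed seed, 20× inflated sample) until the
  pooled Spearman matrix matches the configured targets, e.g. 0.396 for
  pancreas–heart.
* *Unreported pairs.* Ferritin's correlations with LIC and pancreatic T2\*
  are not reported. Ferritin–LIC is set to 0.75, a field-realistic value for
  transfusion-dependent cohorts that is also the one consistent with the
  reported regression structure: LIC has a strong univariate association
  with heart T2\* yet drops out of the multivariate model, i.e. its effect
  is mediated by ferritin and pancreatic iron.

`calibrate_mio_prevalence()` pins the per-group myocardial-overload counts
(1/75, 3/96, 23/107) exactly: the group is split between its k-th and
(k+1)-th heart-T2\* order statistics and only the side of the split on the
wrong side of 20 ms is moved onto it (downward moves are multiplicative to
preserve positivity). The transform is monotone and rank-preserving, touches
only the tail, and leaves group moments essentially intact — a whole-group
location shift would distort the sufficient group badly, since 1/75 below
20 ms is essentially an outlier relative to its N(40.9, 6.0) bulk. The
low-segment count is then re-derived from the global value as
`round(16 Φ((20 − T2*)/3))`, i.e. assuming segmental values spread ~3 ms
around the global mean, which reproduces the reported group means of that
count to within sampling error.

**What the synthetic data do not show.** Phantoms have piecewise-constant
truth, no susceptibility gradients, no motion, and contours are exact;
passing phantom tests validates the numerics, not robustness to real
artefacts. The cohort matches margins and pairwise rank correlations only —
no transfusion/chelation history, no longitudinal structure, and
higher-order dependence is whatever the Gaussian copula implies. Statistics
validated on it (e.g. the stepwise retained set) are statements about the
calibrated generative structure, not new clinical evidence.

## Numerical choices and problem sizes

* Fitting tolerances: LM `ftol 1e-15 / ptol 1e-10`, up to 1024 iterations.
* Phantom validation uses a 128×128 grid at image noise σ/S0 = 0.02, where
  per-segment ROI means support a 3% recovery tolerance.
* The relaxometry error property is tested on ROI-mean decays (100-pixel
  ROIs) at σ/S0 = 0.02. At σ/S0 = 0.05 a T2\* = 2 ms decay keeps only two
  echoes above the noise floor at SNR ≤ 6.5 and Rician bias alone exceeds
  10%; no magnitude-domain fit meets a 5% median there, which we record as a
  known limitation of short-T2\* fitting at high noise.
* Monte-Carlo suites use 100–200 fixed-seed replicates; the cohort-level
  checks (ROC band, stepwise retained set, BIC-oracle agreement) use 100
  seeded cohorts of n = 278 each, sized to keep the full test run around a
  minute.
* Ties in the Youden criterion go to the cut-off with higher sensitivity;
  ROC thresholds are the observed values only.
* `nearPD` repair is applied to the latent correlation target; a target that
  is not positive-definite after repair is an error, not a silent fix.
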