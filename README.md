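# ferriscope

Quantitative MRI iron assessment and cohort analytics for transfusion-dependent
anemias, in R.

Patients with beta-thalassemia major accumulate iron in the heart, liver and
pancreas from lifelong transfusions. The clinical standard for monitoring that
burden is multi-echo gradient-echo MRI: tissue iron shortens the effective
transverse relaxation time T2\*, so fitting the per-echo signal decay
`S(TE) = S0 * exp(-TE / T2*) + C` in a region of interest measures iron
non-invasively (low T2\* = high iron). `ferriscope` implements that measurement
chain and the epidemiological statistics built on top of it:

- **Relaxometry** — ROI-mean decay extraction, the constant-offset
  mono-exponential model, and a truncation model for heavily iron-loaded
  tissue that discards late echoes below the noise floor
  (`roi_mean_decay()`, `fit_offset_model()`, `fit_truncated_model()`,
  `select_fit()`); liver iron concentration from hepatic T2\* via a
  calibration linear in R2\* = 1000/T2\* (`lic_from_liver_t2star()`), and the
  three-ROI pancreatic mean (`pancreas_global()`).
- **Cardiac mapping** — the AHA 16-segment left-ventricular model
  (6 basal + 6 mid + 4 apical equiangular sectors) from endo/epicardial
  contours, per-segment fits, global heart T2\* and the count of segments at
  or below the 20 ms normality threshold (`segment_masks()`,
  `build_heart_map()`).
- **Ventricular function** — Simpson's-rule disc summation, ejection fraction
  `(EDV - ESV) * 100 / EDV`, LV mass at 1.05 g/cm3, Du Bois / Mosteller BSA
  indexing (`simpson_volume()`, `ejection_fraction()`, `lv_mass()`,
  `ventricular_metrics()`).
- **Classification** — vitamin-D status (deficient < 20, insufficient 20-29,
  sufficient >= 30 ng/mL), organ iron-overload flags (LIC >= 3 mg/g dw,
  pancreatic T2\* < 26 ms, heart T2\* <= 20 ms), PTH status
  (`classify_cohort()`, `iron_thresholds()`).
- **Cohort statistics** — normality-routed group comparisons with Bonferroni
  pairwise correction, Pearson/Spearman correlation, Woolf/logistic 2x2 odds
  ratios, univariate screen + forward stepwise regression with VIF/tolerance
  diagnostics, and empirical ROC with DeLong CI and Youden-index cut-offs
  (`compare_groups()`, `odds_ratio_2x2()`, `stepwise_t2star_model()`,
  `roc_youden()`).
- **Synthetic data** — seeded multi-echo phantoms with Rician noise and known
  per-region T2\*, and a Gaussian-copula synthetic cohort of 278 patients
  with the three vitamin-D groups' sizes, moments and cross-organ rank
  correlations (`make_phantom()`, `generate_cohort()`,
  `calibrate_mio_prevalence()`), so the whole chain runs without protected
  clinical data.
- **Pipeline** — batch image-to-metrics orchestration with per-patient
  continue-on-error, and a one-call cohort report (descriptives, three-group
  comparisons, OR panel, stepwise model, ROC) serializable to JSON and
  markdown (`run_image_pipeline()`, `run_cohort_analysis()`).

Fitted objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` methods; data-frame-first signatures chain with the pipe.

## Worked example

```r
library(ferriscope)

# A myocardial decay measured at 10 echoes spaced 2.26 ms
te <- default_echo_times()
fit <- select_fit(echo_series(te, 100 * exp(-te / 20) + 5))
glance(fit)
#> # A tibble: 1 x 7
#>   t2star    s0 offset model  n_echoes_used     rmse r_squared
#>    <dbl> <dbl>  <dbl> <chr>          <int>    <dbl>     <dbl>
#> 1   20.0   100   5.00 offset            10 7.45e-15         1

# T2* of 20 ms sits exactly on the conservative myocardial threshold: a
# heart at that value is flagged as overloaded (normal is strictly > 20 ms).

# Odds ratio of myocardial iron overload, deficient vs insufficient vitamin D,
# from the group counts (23/107 vs 3/96):
odds_ratio_2x2(23, 84, 3, 93)
#> # A tibble: 1 x 5
#>   or_value ci_low ci_high log_se  p_value
#>      <dbl>  <dbl>   <dbl>  <dbl>    <dbl>
#> 1     8.49   2.46    29.3  0.632 0.000715

# Full synthetic-cohort analysis
cfg <- cohort_config()
cohort <- generate_cohort(cfg, seed = 7) |>
  calibrate_mio_prevalence() |>
  classify_cohort()
report <- run_cohort_analysis(cohort)
report$regression
#> <stepwise_report> outcome = heart_t2star | retained: ferritin,
#>   pancreas_t2star, vitamin_d | F = 44.809, p = 1.36e-23
report$roc
#> <roc_report> AUC = 0.798 (95% CI 0.720-0.876) | cutoff <= 16.97:
#>   sens 85.2%, spec 74.1%
```

The deficient-vitamin-D group carries an eight-fold higher odds of myocardial
iron overload than the insufficient group; in the synthetic cohort the
stepwise model retains ferritin, vitamin D and pancreatic T2\* as the
determinants of global heart T2\*, and vitamin D discriminates myocardial
overload with an AUC near 0.8 at a cut-off in the high-teens ng/mL — the
structure the generator is calibrated to emulate.

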