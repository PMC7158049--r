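# dcerisk

Voxelwise pharmacokinetic analysis of dynamic contrast-enhanced MRI
(DCE-MRI) and survival-driven selection of imaging biomarkers, aimed at the
question that motivates DCE-MRI in locally advanced cervical carcinoma: does
the extent of the poorly-perfused (candidate hypoxic) tumour subvolume
predict disease-free and overall survival?

The package implements, end to end:

* **Standard Tofts model** fitting per voxel against the population
  biexponential arterial input function
  `Cp(t) = A·e^(−Bt) + C·e^(−Dt)` (A = 5.10 mM, B = 14.2 s⁻¹, C = 0.99 mM,
  D = 0.159 s⁻¹), via closed-form evaluation of
  `Ct(T) = Ktrans ∫₀ᵀ Cp(t)·e^(−kep(T−t)) dt` and Levenberg–Marquardt least
  squares with multi-start initialisation, producing `Ktrans` and `ve` maps.
* **Signal-to-concentration conversion** for spoiled gradient-echo series
  (TR 160 ms, TE 3.5 ms, flip 90°), either as tube-calibrated linear
  relative enhancement (two-chamber calibration: saline and 0.5 mM
  Gd-DTPA) or full SPGR inversion.
* **Frequency-distribution biomarkers**: nearest-rank percentile values
  (e.g. the 35th-percentile `Ktrans`) and threshold-defined **risk
  volumes** `RV-Ktrans` (tumour subvolume with `Ktrans` strictly below a
  threshold, the reference optimum being 0.13 min⁻¹), plus non-model-based
  proxies (early low-enhancement volume, late increasing-signal volume) and
  T2-based exclusion of air/fluid voxels.
* **Biomarker selection**: one-third/two-thirds cohort splits (80 patients
  → 26 vs 54), log-rank sweeps over integer percentiles 1–99 and over
  `Ktrans` thresholds up to 0.50 min⁻¹ in 0.0025 min⁻¹ steps, and optimum
  selection by ROC AUC; Kaplan–Meier, Cox proportional hazards and Spearman
  correlation for validation.
* **Digital phantoms and synthetic cohorts** with known ground truth —
  spatially correlated `Ktrans`/`ve` fields, a planted low-`Ktrans`
  subvolume, necrosis visible on a synthetic T2 volume, a simulated
  two-chamber calibration tube, and survival times whose hazard depends on
  the planted risk volume — so that every stage is testable without any
  clinical data.

Functions are tidyverse-style: tabular stages take and return tibbles,
fitted objects have `tidy()` / `glance()` methods, result objects have
`autoplot()` methods; images (phantoms, 4-D series, parameter maps) are
lightweight array-backed objects with `as_tibble()` converters and NIfTI
I/O.

## A worked example

Simulate a 40-patient synthetic cohort (hazard ratio 3 for patients with
large planted risk volumes), compute per-patient biomarkers, and sweep
thresholds and percentiles:

```r
library(dcerisk)

run <- run_pipeline(
  cohort_config(n_patients = 40, hazard_ratio = 3, seed = 11),
  phantom_config(grid_shape = c(12, 12, 4)),
  thresholds = threshold_grid(step = 0.01),
  percentiles = seq(5, 95, by = 5))

run$optima
#> # A tibble: 4 × 6
#>   endpoint optimum   auc logrank_p agrees_other_endpoint axis_type
#>   <chr>      <dbl> <dbl>     <dbl> <lgl>                 <chr>
#> 1 dfs        20    0.655    0.306  TRUE                  percentile
#> 2 os         20    0.668    0.267  TRUE                  percentile
#> 3 dfs         0.13 0.689    0.0449 TRUE                  threshold
#> 4 os          0.13 0.708    0.0401 TRUE                  threshold
```

The threshold sweep's AUC-selected optimum lands on the planted threshold,
0.13 min⁻¹, for both endpoints, with log-rank p < 0.05 at the optimum —
even in this small, fast example (the 12 × 12 × 4 phantom grid keeps it
under a couple of seconds). Univariate Cox models for the derived
biomarkers:

```r
run$cox
#> # A tibble: 6 × 8
#>   endpoint term             estimate hazard_ratio std_error statistic p_value flagged
#> 1 dfs      rv_ktrans_cm3        5.40    221.           3.43     1.57   0.116  FALSE
#> 2 os       rv_ktrans_cm3        5.97    393.           3.46     1.73   0.0841 FALSE
#> 3 dfs      p_ktrans            -2.80      0.0606       7.29    -0.385  0.701  FALSE
#> 4 os       p_ktrans            -4.97      0.00694      7.57    -0.657  0.511  FALSE
#> 5 dfs      tumor_volume_cm3    NA        NA            0       NA     NA      TRUE
#> 6 os       tumor_volume_cm3    NA        NA            0       NA     NA      TRUE
```

Risk volume carries the survival signal (positive log hazard ratio: larger
risk volume, worse outcome; the 35th-percentile value points the expected
way — low values mark risk). Tumour volume is constant by construction in
this equal-grid cohort, and the Cox wrapper *flags* the degenerate fit
rather than returning it silently. `autoplot(run$threshold_sweep)` draws
the p-value and AUC curves; `plot_km()` draws Kaplan–Meier curves for any
grouping.

Lower-level entry points mirror the pipeline stages: `generate_phantom()`,
`simulate_dce_series()`, `concentration_from_signal()`,
`fit_tofts_volume()`, `frequency_distribution()`, `percentile_value()`,
`risk_volume()`, `percentile_sweep()`, `threshold_sweep()`,
`select_optimum()`, `km_fit()`, `logrank_test()`, `cox_fit()`,
`roc_auc()`, `spearman_test()`. See the methods vignette
(`vignettes/dcerisk-methods.Rmd`) for the models, conventions and design
decisions.

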