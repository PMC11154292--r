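# echowall

Carotid artery wall **echolucency** — how dark the wall appears on B-mode
ultrasound — marks tissue composition: dark (echolucent) plaques are
lipid-rich and rupture-prone, bright (echogenic) walls fibrous or
calcified. `echowall` implements, as a tested and reusable R pipeline, the
quantification of echolucency as the **gray-scale median (GSM)** and the
epidemiological analysis of its determinants, for researchers working with
multicenter carotid ultrasound cohorts.

The pipeline covers:

* **Measurement** — GSM as the 50th percentile of ROI pixel gray levels
  (0–255), per-image black/white calibration (lumen → 0, adventitia → 190),
  the darkest-of-the-two-thickest plaque rule across left/right carotids,
  left/right averaging for the plaque-free intima–media complex (IM-GSM),
  a priori residualization of GSM on the calibration references, and
  scan–rescan reproducibility (mean absolute difference; one-way
  random-effects ICC).
* **Determinant selection** — pack-years coding (0 / tertiles 1–3 among
  ever-smokers), a quartile-stratified univariate screen
  (ANOVA / Kruskal–Wallis / χ² / Fisher, Bonferroni threshold p < 0.0007),
  and a 200-iteration split-sample **stability selection**: forward
  stepwise on a random training half, per-coefficient validation
  (p < 0.05) on the testing half, retention at ≥ 70% validated frequency;
  then a final multiple regression with semi-standardized betas (outcome
  units per predictor SD) and an additive sequential **partial R²**
  decomposition that sums exactly to the whole-model R².
* **Risk stratification** — Pearson correlation of the two GSM phenotypes,
  logistic prediction of median-dichotomized GSM with ROC AUC comparison
  (subject-level bootstrap of the paired AUC difference), and quartile
  odds-ratio analyses for high atherosclerotic burden (IMT_max in the
  upper quartile): an ordinal per-quartile OR and a 4×4 plaque-GSM ×
  IM-GSM grid against the (plaque Q4, IM Q1) reference cell, adjusted for
  latitude, sex, age, educational level, pulse pressure and pack-years
  code.
* **Synthetic cohort** — a generator emulating a five-country European
  high-cardiovascular-risk cohort (n = 3188, exactly 2138 plaque-eligible),
  with configurable per-predictor incremental R², cross-phenotype
  correlation 0.51, injected per-quartile burden ORs (0.79 / 1.12),
  scan–rescan ICC targets (0.75 / 0.83), speckled wall images with
  ground-truth masks, and a 73-column screened candidate panel — so every
  stage is testable against known ground truth without any data download.

Functions take a data frame first and return tibbles; fitted objects have
`tidy()` / `glance()` methods and `autoplot()` figures. A thin command-line
wrapper lives at `inst/scripts/echowall.R`
(`simulate | measure | select | stratify | report | all`).

## A worked example

```r
library(echowall)
library(dplyr)

cohort <- cohort_config(seed = 42) |>
  generate_cohort() |>
  adjust_cohort_gsm()

c(nrow(cohort), sum(cohort$plaque_present))
#> [1] 3188 2138

fit <- cohort |>
  filter(plaque_present) |>
  fit_final_model("plaque_gsm", effect_table_plaque()$predictor)
tidy(fit)
#> # A tibble: 4 × 7
#>   term            estimate std_error statistic  p_value partial_r2 partial_cor2
#> 1 latitude          -2.46      0.200    -12.3  1.66e-33    0.0712       0.0660
#> 2 dbp                1.17      0.198      5.93 3.54e- 9    0.0148       0.0162
#> 3 imt_max_q         -1.00      0.201     -4.99 6.59e- 7    0.00950      0.0115
#> 4 pack_years_code    0.782     0.198      3.94 8.29e- 5    0.00655      0.00724

correlate_gsm(cohort)
#> # A tibble: 1 × 5
#>       r   p_value conf_low conf_high     n
#> 1 0.511 1.83e-142    0.479     0.542  2138

or_per_quartile(cohort, "plaque")
#> # A tibble: 1 × 6
#>   which     or conf_low conf_high      p_value     n
#> 1 plaque 0.753    0.684     0.830 0.0000000101  2138

reproducibility_stats(generate_repeat_scans(cohort, "im", seed = 1))
#> # A tibble: 1 × 4
#>       n mean_abs_diff sd_abs_diff   icc
#> 1   138          5.71        4.03 0.848
```

Reading the output: each predictor's `estimate` is the change in plaque-GSM
(gray levels) per one SD of the predictor — northern latitude and thicker
lesions make plaques darker, higher diastolic pressure and smoking exposure
make them brighter — and `partial_r2` is its additive share of explained
variance (this single cohort realizes 7.1% for latitude; the generative
value is 8.7%). The two phenotypes correlate at r ≈ 0.51, and the odds of
a high atherosclerotic burden fall by a factor ≈ 0.75 per plaque-GSM
quartile after covariate adjustment.

An end-to-end run (cohort CSV, selection reports, model tables, OR grid,
figures, Markdown report, manifest):

```r
res <- run_pipeline(run_config(seed = 1), dir = "runs/demo")
```

## Documentation

The methods vignette (`vignettes/echowall-methods.Rmd`) describes the
measurement model, the selection procedure, the generator's design and its
limitations in detail.
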