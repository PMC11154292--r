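#' Recruitment centers of the emulated cohort
#'
#' Five European countries with a north-to-south latitude gradient. Weights
#' are the per-country recruitment shares of the 3188-subject analysis
#' cohort (Finland one remaining center; Italy two centers pooled).
#'
#' @return Tibble with `center`, `latitude` (degrees North) and `weight`.
#' @export
improve_centers <- function() {
  tibble::tibble(
    center   = c("Finland", "Sweden", "Netherlands", "France", "Italy"),
    latitude = c(62.9, 59.3, 53.0, 48.9, 44.3),
    weight   = c(533, 532, 527, 501, 1095) / 3188
  )
}

#' Effect structure of the plaque-GSM determinant model
#'
#' Per-predictor signs and incremental (partial) R-squared targets for the
#' four independent determinants of plaque echolucency. `beta_printed` is the
#' reported semi-standardized coefficient (GSM units per predictor SD), kept
#' for reference; the generator's effective coefficient is
#' `sign(beta) * sqrt(partial_r2) * gsm_sd` so that the R-squared
#' decomposition is reproduced exactly (see the methods vignette).
#'
#' @return Tibble with `predictor`, `beta_printed`, `partial_r2`.
#' @export
effect_table_plaque <- function() {
  tibble::tibble(
    predictor    = c("latitude", "dbp", "imt_max_q", "pack_years_code"),
    beta_printed = c(-3.23, 1.36, -0.96, 0.85),
    partial_r2   = c(0.087, 0.017, 0.008, 0.007)
  )
}

#' Effect structure of the IM-GSM determinant model
#'
#' Eleven independent determinants of the echolucency of the plaque-free
#' common-carotid intima-media complex. Same conventions as
#' [effect_table_plaque()].
#'
#' @return Tibble with `predictor`, `beta_printed`, `partial_r2`.
#' @export
effect_table_im <- function() {
  tibble::tibble(
    predictor = c(
      "latitude", "height", "sbp", "pf_cc_imt_q", "waist_hip_ratio",
      "fibrates", "pack_years_code", "mcv", "sartans",
      "educational_level", "creatinine_log"
    ),
    beta_printed = c(-4.27, 1.50, 1.44, -1.85, -1.93, -0.95, 0.93,
                     -0.79, -0.79, -0.79, 0.96),
    partial_r2 = c(0.111, 0.020, 0.015, 0.012, 0.010, 0.006, 0.006,
                   0.005, 0.005, 0.004, 0.004)
  )
}

# Distributional defaults for the covariate panel. The source study's
# descriptive appendix is not reproduced here, so these are plausible
# values for a high-cardiovascular-risk European cohort aged 54-79;
# all are config-exposed.
default_covariate_params <- function() {
  list(
    age_mean = 64, age_sd = 5.5, age_range = c(54, 79),
    male_fraction = 0.46,
    height = c(169, 9), whr = c(0.92, 0.08),
    sbp_mean = 142, sbp_sd = 19,
    dbp_mean = 82, dbp_sd = 10, sbp_dbp_rho = 0.7,
    ever_smoker_fraction = 0.55,
    pack_years_shape = 1.6, pack_years_scale = 14,
    education_mean = 11, education_sd = 4,
    creatinine_logmean = log(80), creatinine_logsd = 0.18,
    mcv_mean = 90, mcv_sd = 5,
    fibrates_fraction = 0.07, sartans_fraction = 0.14,
    pf_imt_mean = 0.71, pf_imt_sd = 0.11, pf_imt_severity_rho = 0.5
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: cohort size, plaque
#' prevalence, the five-country latitude mixture, the effect structure of the
#' two GSM outcome models, the cross-outcome correlation, the per-quartile
#' burden odds ratios, and the scan-rescan reliability targets.
#'
#' @param n_subjects Number of subjects (default 3188).
#' @param plaque_fraction Fraction with at least one lesion of maximum
#'   intima-media thickness >= 1.5 mm (default 2138/3188); the generated
#'   count is exact, not an expectation.
#' @param centers Tibble of recruitment centers, see [improve_centers()].
#' @param effect_plaque,effect_im Effect tables for the two outcomes, see
#'   [effect_table_plaque()] and [effect_table_im()].
#' @param gsm_means,gsm_sds Named (`plaque`, `im`) marginal means and SDs of
#'   the calibrated GSM outcomes, in gray levels.
#' @param cross_gsm_rho Target marginal Pearson correlation between
#'   plaque-GSM and IM-GSM among plaque-eligible subjects.
#' @param or_quartile Named (`plaque`, `im`) target adjusted odds ratios for
#'   high atherosclerotic burden per one-quartile GSM increase, each as
#'   recovered by a single-GSM ordinal logistic model with the standard
#'   adjustment covariates.
#' @param burden_covariate_logor Named log-odds (per covariate SD) of the
#'   adjustment covariates in the latent burden model.
#' @param icc_targets Named (`plaque`, `im`) scan-rescan intraclass
#'   correlation targets.
#' @param calibration_leak Named (`black`, `white`) residual linear leakage
#'   of the calibration references into the raw GSM values (gray levels per
#'   gray level), removed downstream by [adjust_for_calibration()].
#' @param covariate_params List of covariate distribution parameters, see
#'   `default_covariate_params`.
#' @param n_nuisance Number of null candidate columns added to emulate the
#'   screened covariate panel.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A `cohort_config` list.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 200, seed = 1)
#' cfg$plaque_fraction
cohort_config <- function(n_subjects = 3188L,
                          plaque_fraction = 2138 / 3188,
                          centers = improve_centers(),
                          effect_plaque = effect_table_plaque(),
                          effect_im = effect_table_im(),
                          gsm_means = c(plaque = 30.6, im = 43.8),
                          gsm_sds = c(plaque = 9.9, im = 11.7),
                          cross_gsm_rho = 0.51,
                          or_quartile = c(plaque = 0.79, im = 1.12),
                          burden_covariate_logor = c(
                            latitude = 0.4, sex_male = 0.3, age = 0.3,
                            educational_level = -0.15, pulse_pressure = 0.25,
                            pack_years_code = 0.2
                          ),
                          icc_targets = c(plaque = 0.75, im = 0.83),
                          calibration_leak = c(black = 0.10, white = 0.05),
                          covariate_params = default_covariate_params(),
                          n_nuisance = 60L,
                          seed = 42L) {
  stopifnot(
    n_subjects >= 1,
    plaque_fraction > 0, plaque_fraction <= 1,
    cross_gsm_rho > -1, cross_gsm_rho < 1,
    all(icc_targets > 0), all(icc_targets < 1),
    all(or_quartile > 0),
    n_nuisance >= 0
  )
  for (tab in list(effect_plaque, effect_im)) {
    if (any(tab$partial_r2 < 0) || sum(tab$partial_r2) >= 1) {
      stop("infeasible effect table: partial R-squared values must be >= 0 and sum to < 1",
           call. = FALSE)
    }
    if (anyDuplicated(tab$predictor)) {
      stop("duplicate predictor in effect table", call. = FALSE)
    }
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      plaque_fraction = plaque_fraction,
      centers = centers,
      effect_plaque = effect_plaque,
      effect_im = effect_im,
      gsm_means = gsm_means,
      gsm_sds = gsm_sds,
      cross_gsm_rho = cross_gsm_rho,
      or_quartile = or_quartile,
      burden_covariate_logor = burden_covariate_logor,
      icc_targets = icc_targets,
      calibration_leak = calibration_leak,
      covariate_params = covariate_params,
      n_nuisance = as.integer(n_nuisance),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  subjects:       ", x$n_subjects,
      " (", round(x$n_subjects * x$plaque_fraction), " plaque-eligible)\n", sep = "")
  cat("  outcomes:        plaque-GSM ", x$gsm_means[["plaque"]], " ± ",
      x$gsm_sds[["plaque"]], "; IM-GSM ", x$gsm_means[["im"]], " ± ",
      x$gsm_sds[["im"]], "\n", sep = "")
  cat("  effects:        ", nrow(x$effect_plaque), "plaque +",
      nrow(x$effect_im), "IM predictors,", x$n_nuisance, "nuisance columns\n")
  cat("  seed:           ", x$seed, "\n")
  invisible(x)
}
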