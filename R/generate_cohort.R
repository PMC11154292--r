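#' Generate a synthetic high-cardiovascular-risk cohort
#'
#' Simulates one subject-level table with the statistical structure the
#' echolucency analysis assumes: a five-country latitude mixture, vascular
#' risk factors and treatments, an exact count of plaque-eligible subjects
#' (maximum intima-media thickness >= 1.5 mm), two GSM outcomes that are
#' linear in the configured standardized predictors with incremental
#' R-squared equal to the configured targets, cross-outcome residual
#' correlation calibrated to the target marginal correlation, a latent
#' logistic burden model with injected per-quartile log odds ratios, raw GSM
#' values carrying a small linear leakage of the per-image calibration
#' references, and independent nuisance candidate columns.
#'
#' The simulation ground truth is kept in the `plaque_gsm_true` and
#' `im_gsm_true` columns (calibration-free outcome values) so downstream
#' stages can be tested against an oracle.
#'
#' @param config A [cohort_config()].
#' @return Tibble with one row per subject; the config is attached as
#'   attribute `"config"`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 400, seed = 7))
#' sum(cohort$plaque_present)
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  p <- config$covariate_params

  centers <- config$centers
  idx_center <- sample.int(nrow(centers), n, replace = TRUE, prob = centers$weight)
  center <- centers$center[idx_center]
  latitude <- centers$latitude[idx_center]

  age <- pmin(pmax(rnorm(n, p$age_mean, p$age_sd), p$age_range[1]), p$age_range[2])
  sex_male <- rbinom(n, 1, p$male_fraction)
  # predictors are drawn independently so the configured incremental
  # R-squared values stay additive across the model
  height <- rnorm(n, p$height[1], p$height[2])
  waist_hip_ratio <- rnorm(n, p$whr[1], p$whr[2])
  z1 <- rnorm(n); z2 <- rnorm(n)
  sbp <- p$sbp_mean + p$sbp_sd * z1
  dbp <- p$dbp_mean + p$dbp_sd * (p$sbp_dbp_rho * z1 + sqrt(1 - p$sbp_dbp_rho^2) * z2)
  pulse_pressure <- sbp - dbp
  ever <- rbinom(n, 1, p$ever_smoker_fraction)
  pack_years <- ever * rgamma(n, shape = p$pack_years_shape, scale = p$pack_years_scale)
  pack_years_code <- code_pack_years(pack_years)
  educational_level <- pmax(0, round(rnorm(n, p$education_mean, p$education_sd)))
  creatinine <- exp(rnorm(n, p$creatinine_logmean, p$creatinine_logsd))
  creatinine_log <- log(creatinine)
  mcv <- rnorm(n, p$mcv_mean, p$mcv_sd)
  fibrates <- rbinom(n, 1, p$fibrates_fraction)
  sartans <- rbinom(n, 1, p$sartans_fraction)

  # Latent lesion severity drives plaque eligibility (exact count) and the
  # provisional thickness ordering; plaque-free CC thickness is correlated.
  imt_latent <- rnorm(n)
  pf_cc_imt_mean <- p$pf_imt_mean + p$pf_imt_sd *
    (p$pf_imt_severity_rho * imt_latent +
       sqrt(1 - p$pf_imt_severity_rho^2) * rnorm(n))
  n_plaque <- round(n * config$plaque_fraction)
  plaque_present <- rep(FALSE, n)
  plaque_present[order(imt_latent, decreasing = TRUE)[seq_len(n_plaque)]] <- TRUE

  black_ref <- sample(0:37, n, replace = TRUE)
  white_ref <- sample(104:255, n, replace = TRUE)

  nuis <- NULL
  if (config$n_nuisance > 0) {
    nuis <- matrix(rnorm(n * config$n_nuisance), n, config$n_nuisance,
                   dimnames = list(NULL, sprintf("nuis%02d", seq_len(config$n_nuisance))))
  }

  cohort <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    center, latitude, age, sex_male, height, waist_hip_ratio,
    sbp, dbp, pulse_pressure, pack_years, pack_years_code,
    educational_level, creatinine, creatinine_log, mcv, fibrates, sartans,
    pf_cc_imt_mean, plaque_present,
    black_ref, white_ref
  )
  if (!is.null(nuis)) cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(nuis))

  pl <- plaque_present
  cohort$pf_cc_imt_q <- quartile_code(pf_cc_imt_mean)

  # --- outcome construction -------------------------------------------------
  # The plaque thickness quartile ("imt_max_q") gets no direct coefficient:
  # its association with plaque-GSM emerges from the burden construction
  # below (darker plaques are steered into the top thickness quartile), and
  # at the configured per-quartile OR that emergent association reproduces
  # the small thickness partial R-squared of the determinant model.
  sd_p <- config$gsm_sds[["plaque"]]; sd_i <- config$gsm_sds[["im"]]
  mu_p <- config$gsm_means[["plaque"]]; mu_i <- config$gsm_means[["im"]]
  eff_p <- config$effect_plaque; eff_i <- config$effect_im
  beta_p <- sign(eff_p$beta_printed) * sqrt(eff_p$partial_r2) * sd_p
  beta_i <- sign(eff_i$beta_printed) * sqrt(eff_i$partial_r2) * sd_i
  sig_ep <- sd_p * sqrt(1 - sum(eff_p$partial_r2))
  sig_ei <- sd_i * sqrt(1 - sum(eff_i$partial_r2))

  im_cols <- eff_i$predictor
  Zi <- standardize_cols(as.data.frame(cohort)[im_cols])
  L_i <- drop(Zi %*% beta_i)

  direct_p <- setdiff(eff_p$predictor, "imt_max_q")
  Zp <- standardize_cols(as.data.frame(cohort)[pl, direct_p, drop = FALSE])
  L_p <- drop(Zp %*% beta_p[match(direct_p, eff_p$predictor)])

  # residuals: correlation calibrated so the marginal plaque/IM correlation
  # among plaque-eligible subjects hits the configured target
  e_i <- rnorm(n, 0, sig_ei)
  covL <- cov(L_p, L_i[pl])
  sd_tot_p <- sqrt(var(L_p) + sig_ep^2)
  sd_tot_i <- sqrt(var(L_i[pl]) + sig_ei^2)
  rho_res <- (config$cross_gsm_rho * sd_tot_p * sd_tot_i - covL) / (sig_ep * sig_ei)
  if (abs(rho_res) > 0.99) {
    warning("residual correlation clipped to +/-0.99; marginal correlation target may not be met")
    rho_res <- sign(rho_res) * 0.99
  }
  e_p <- rho_res * (sig_ep / sig_ei) * e_i[pl] +
    sig_ep * sqrt(1 - rho_res^2) * rnorm(n_plaque)

  plaque_gsm_true <- mu_p + L_p + e_p
  im_gsm_true <- mu_i + L_i + e_i

  # --- latent burden model and final IMT_max --------------------------------
  pq <- quartile_code(plaque_gsm_true)
  iq <- quartile_code(im_gsm_true[pl])
  W <- standardize_cols(data.frame(
    latitude = latitude[pl], sex_male = sex_male[pl], age = age[pl],
    educational_level = educational_level[pl],
    pulse_pressure = pulse_pressure[pl], pack_years_code = pack_years_code[pl]
  ))
  gam <- config$burden_covariate_logor[colnames(W)]
  # partial correlation of the two quartile codes given the covariates,
  # used to convert the target marginal per-quartile ORs into joint
  # coefficients of the latent burden model
  rp <- residuals(lm(pq ~ W)); ri <- residuals(lm(iq ~ W))
  rho_q <- cor(rp, ri)
  lp <- log(config$or_quartile[["plaque"]]); li <- log(config$or_quartile[["im"]])
  b_pq <- (lp - rho_q * li) / (1 - rho_q^2)
  b_iq <- (li - rho_q * lp) / (1 - rho_q^2)
  s <- b_pq * pq + b_iq * iq + drop(W %*% gam) + rlogis(n_plaque)
  high_burden <- s >= quantile(s, 0.75, type = 7)

  # final IMT_max: high-burden subjects occupy the top quartile of the
  # plaque thickness distribution; within groups order follows the latent
  # severity; plaque-free subjects stay below the 1.5 mm lesion threshold
  imt_max <- rep(NA_real_, n)
  rk <- integer(n_plaque)
  rk[!high_burden] <- rank(imt_latent[pl][!high_burden])
  rk[high_burden] <- sum(!high_burden) + rank(imt_latent[pl][high_burden])
  u_pl <- (rk - 0.5) / n_plaque
  imt_max[pl] <- 1.5 + 0.72 * (-log(1 - 0.995 * u_pl))
  u_np <- (rank(imt_latent[!pl]) - 0.5) / sum(!pl)
  imt_max[!pl] <- 0.4 + 1.09 * u_np

  imt_qf <- rep(NA_integer_, n)
  imt_qf[pl] <- quartile_code(imt_max[pl])

  cohort$imt_latent <- imt_latent
  cohort$imt_max <- imt_max
  cohort$imt_max_q <- imt_qf
  cohort$plaque_gsm_true <- NA_real_
  cohort$plaque_gsm_true[pl] <- plaque_gsm_true
  cohort$im_gsm_true <- im_gsm_true

  # raw GSM = true value + residual calibration leakage, clipped to gray range
  leak <- config$calibration_leak
  lk <- leak[["black"]] * (black_ref - mean(0:37)) +
    leak[["white"]] * (white_ref - mean(104:255))
  cohort$plaque_gsm_raw <- pmin(pmax(cohort$plaque_gsm_true + lk, 0), 255)
  cohort$im_gsm_raw <- pmin(pmax(cohort$im_gsm_true + lk, 0), 255)

  attr(cohort, "config") <- config
  cohort
}

#' A priori calibration adjustment of a generated cohort
#'
#' Adds `plaque_gsm` and `im_gsm` columns: the raw GSM values residualized
#' on the per-image reference black and white levels (and re-centered), the
#' form in which the determinant and risk analyses use them.
#'
#' @param cohort Tibble from [generate_cohort()] (or any table with
#'   `plaque_gsm_raw`, `im_gsm_raw`, `black_ref`, `white_ref`).
#' @return The cohort with adjusted GSM columns appended.
#' @export
adjust_cohort_gsm <- function(cohort) {
  cohort$plaque_gsm <- adjust_for_calibration(
    cohort$plaque_gsm_raw, cohort$black_ref, cohort$white_ref
  )
  cohort$im_gsm <- adjust_for_calibration(
    cohort$im_gsm_raw, cohort$black_ref, cohort$white_ref
  )
  cohort
}

#' Generate scan-rescan measurement pairs
#'
#' Draws a reproducibility subsample and simulates two scans per subject:
#' the subject's underlying GSM plus independent measurement error with
#' variance chosen so that the intraclass correlation
#' (between-subject variance over total) equals the target.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param outcome `"plaque"` or `"im"`: which GSM is re-scanned (plaque
#'   restricts the sampling frame to plaque-eligible subjects).
#' @param icc_target Target intraclass correlation in (0, 1); defaults to
#'   the configured value for `outcome`.
#' @param n Subsample size (default 138).
#' @param seed Optional seed for the subsample and error draws.
#' @return Tibble with `subject_id`, `scan1`, `scan2`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 400, seed = 3))
#' pairs <- generate_repeat_scans(cohort, "im", n = 60, seed = 1)
#' reproducibility_stats(pairs)
generate_repeat_scans <- function(cohort, outcome = c("plaque", "im"),
                                  icc_target = NULL, n = 138L, seed = NULL) {
  outcome <- match.arg(outcome)
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  cfg <- attr(cohort, "config")
  if (is.null(icc_target)) {
    if (is.null(cfg)) stop("icc_target must be given when the cohort has no config attribute",
                           call. = FALSE)
    icc_target <- cfg$icc_targets[[outcome]]
  }
  if (!is.numeric(icc_target) || icc_target <= 0 || icc_target >= 1) {
    stop("icc_target must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  truth <- if (outcome == "plaque") cohort$plaque_gsm_true else cohort$im_gsm_true
  frame <- which(!is.na(truth))
  if (length(frame) < 2) stop("need at least two subjects with the outcome", call. = FALSE)
  n <- min(n, length(frame))
  idx <- sample(frame, n)
  tv <- truth[idx]
  sig_b2 <- var(tv)
  sig_e <- sqrt(sig_b2 * (1 - icc_target) / icc_target)
  tibble::tibble(
    subject_id = cohort$subject_id[idx],
    scan1 = tv + rnorm(n, 0, sig_e),
    scan2 = tv + rnorm(n, 0, sig_e)
  )
}
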