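test_that("generation is deterministic and the plaque count is exact", {
  cfg <- small_config(500, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(sum(a$plaque_present), round(500 * cfg$plaque_fraction))
  # different seed changes the draw
  c2 <- generate_cohort(small_config(500, seed = 12))
  expect_false(identical(a$im_gsm_raw, c2$im_gsm_raw))
  # plaque-only fields defined exactly on plaque-eligible subjects
  expect_true(all(is.na(a$plaque_gsm_raw[!a$plaque_present])))
  expect_true(all(!is.na(a$plaque_gsm_raw[a$plaque_present])))
  expect_true(all(a$imt_max[a$plaque_present] >= 1.5))
  expect_true(all(a$imt_max[!a$plaque_present] < 1.5))
})

test_that("gray levels and calibration references respect their ranges", {
  a <- generate_cohort(small_config(800, seed = 21))
  expect_true(all(a$black_ref >= 0 & a$black_ref <= 37))
  expect_true(all(a$white_ref >= 104 & a$white_ref <= 255))
  expect_true(all(a$black_ref < a$white_ref))
  expect_true(all(a$im_gsm_raw >= 0 & a$im_gsm_raw <= 255))
  ok <- !is.na(a$plaque_gsm_raw)
  expect_true(all(a$plaque_gsm_raw[ok] >= 0 & a$plaque_gsm_raw[ok] <= 255))
  expect_true(all((a$pack_years_code == 0) == (a$pack_years == 0)))
})

test_that("configured effects are recovered by regression within Monte-Carlo error", {
  cohort <- adjust_cohort_gsm(generate_cohort(cohort_config(seed = 31)))
  eff <- effect_table_im()
  fit <- fit_final_model(cohort, "im_gsm", eff$predictor)
  est <- tidy(fit)
  # each semi-standardized beta within 3 SEs of its injected value
  for (j in seq_len(nrow(eff))) {
    inj <- sign(eff$beta_printed[j]) * sqrt(eff$partial_r2[j]) * 11.7
    row <- est[est$term == eff$predictor[j], ]
    expect_lt(abs(row$estimate - inj), 3 * row$std_error)
  }
})

test_that("an all-null effect table yields near-zero candidate R-squared", {
  null_eff_p <- effect_table_plaque()
  null_eff_p$partial_r2 <- rep(0, nrow(null_eff_p))
  null_eff_i <- effect_table_im()
  null_eff_i$partial_r2 <- rep(0, nrow(null_eff_i))
  cohort <- adjust_cohort_gsm(generate_cohort(cohort_config(
    n_subjects = 1500, effect_plaque = null_eff_p, effect_im = null_eff_i,
    seed = 41
  )))
  r2 <- summary(lm(im_gsm ~ latitude + height + sbp, data = cohort))$r.squared
  expect_lt(r2, 0.01)
})

test_that("cross-outcome correlation lands in the closed-form sampling band", {
  rs <- vapply(51:58, function(s) {
    correlate_gsm(adjust_cohort_gsm(generate_cohort(cohort_config(seed = s))))$r
  }, numeric(1))
  n <- round(3188 * 2138 / 3188)
  # every seed inside a 3-sigma Fisher-z band around rho = 0.51 ...
  band <- tanh(atanh(0.51) + c(-1, 1) * 3 / sqrt(n - 3))
  expect_true(all(rs > band[1] & rs < band[2]))
  # ... and the seed average close to the target
  expect_lt(abs(mean(rs) - 0.51), 0.02)
})

test_that("nuisance-column false-positive rate matches alpha over seeds", {
  pvals <- unlist(lapply(1:10, function(s) {
    cohort <- adjust_cohort_gsm(generate_cohort(cohort_config(
      n_subjects = 1000, n_nuisance = 20, seed = 600 + s
    )))
    nn <- grep("^nuis", names(cohort), value = TRUE)
    vapply(nn, function(v) {
      summary(lm(cohort$im_gsm ~ cohort[[v]]))$coefficients[2, 4]
    }, numeric(1))
  }))
  hits <- sum(pvals < 0.05)
  bt <- binom.test(hits, length(pvals), 0.05)
  expect_gt(bt$p.value, 0.001)
})

test_that("infeasible effect tables are rejected", {
  bad <- effect_table_im()
  bad$partial_r2[1] <- 0.99
  expect_error(cohort_config(effect_im = bad), "infeasible")
  expect_error(cohort_config(plaque_fraction = 0), "plaque_fraction")
  expect_error(cohort_config(cross_gsm_rho = 1.2))
})
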