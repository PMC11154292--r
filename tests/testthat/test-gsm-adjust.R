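test_that("calibration adjustment removes black/white correlation exactly", {
  set.seed(2)
  n <- 300
  black <- sample(0:37, n, TRUE)
  white <- sample(104:255, n, TRUE)
  gsm <- 30 + 2 * black + rnorm(n)
  adj <- adjust_for_calibration(gsm, black, white)
  expect_lt(abs(cor(adj, black)), 1e-8)
  expect_lt(abs(cor(adj, white)), 1e-8)
  expect_equal(mean(adj), mean(gsm))
})

test_that("adjustment is a near-identity when GSM is independent of the references", {
  set.seed(4)
  n <- 2000
  black <- sample(0:37, n, TRUE)
  white <- sample(104:255, n, TRUE)
  gsm <- rnorm(n, 40, 10)
  adj <- adjust_for_calibration(gsm, black, white)
  expect_gt(cor(adj, gsm), 0.999)
  fit <- lm(gsm ~ black + white)
  expect_lt(max(abs(coef(fit)[-1])), 0.05)
})

test_that("degenerate constant references return input with a warning", {
  gsm <- c(10, 20, 30, 40)
  expect_warning(out <- adjust_for_calibration(gsm, rep(5, 4), rep(200, 4)),
                 "unchanged")
  expect_equal(out, gsm)
  expect_error(adjust_for_calibration(1:2, 1:2, 1:2), "at least 3")
})

test_that("adjustment preserves NA pattern and handles missing rows", {
  set.seed(5)
  gsm <- c(NA, rnorm(50, 30, 5))
  black <- sample(0:37, 51, TRUE)
  white <- sample(104:255, 51, TRUE)
  adj <- adjust_for_calibration(gsm, black, white)
  expect_true(is.na(adj[1]))
  expect_equal(sum(is.na(adj)), 1)
})

test_that("reproducibility statistics match hand computation", {
  pairs <- tibble::tibble(scan1 = c(1, 5), scan2 = c(3, 9))
  st <- reproducibility_stats(pairs)
  expect_equal(st$mean_abs_diff, 3)
  # identical pairs: zero difference, ICC 1
  same <- tibble::tibble(scan1 = c(10, 20, 30), scan2 = c(10, 20, 30))
  st2 <- reproducibility_stats(same)
  expect_equal(st2$mean_abs_diff, 0)
  expect_equal(st2$icc, 1)
  expect_error(reproducibility_stats(tibble::tibble(scan1 = 1, scan2 = 2)),
               "at least 2")
})

test_that("mean absolute pair difference matches the folded-normal value", {
  # two scans with error SD sigma_e: diff ~ N(0, 2 sigma_e^2),
  # E|diff| = sigma_e * sqrt(2) * sqrt(2/pi)
  sig_e <- 1
  mads <- vapply(1:200, function(s) {
    set.seed(s)
    tv <- rnorm(80, 50, 1)
    reproducibility_stats(tibble::tibble(
      scan1 = tv + rnorm(80, 0, sig_e),
      scan2 = tv + rnorm(80, 0, sig_e)
    ))$mean_abs_diff
  }, numeric(1))
  expect_lt(abs(mean(mads) - sqrt(2) * sqrt(2 / pi)), 0.02)
})

test_that("ICC target corresponds to the generated error variance", {
  cohort <- generate_cohort(small_config(600, seed = 8))
  # icc -> 1 limit: scans nearly identical
  pairs <- generate_repeat_scans(cohort, "im", icc_target = 1 - 1e-10,
                                 n = 50, seed = 1)
  expect_lt(max(abs(pairs$scan1 - pairs$scan2)), 1e-3)
  # mean estimated ICC near target over seeds
  iccs <- vapply(1:40, function(s) {
    reproducibility_stats(
      generate_repeat_scans(cohort, "im", icc_target = 0.75, n = 138,
                            seed = s)
    )$icc
  }, numeric(1))
  expect_lt(abs(mean(iccs) - 0.75), 0.03)
  expect_error(generate_repeat_scans(cohort, "im", icc_target = 1.2),
               "in \\(0, 1\\)")
})
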