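test_that("latitude-strength predictors are retained, pure noise is not", {
  set.seed(77)
  n <- 1200
  d <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 8), n, 8,
    dimnames = list(NULL, c("strong", paste0("noise", 1:7))))))
  # ~8.7% incremental R^2, the strength of the leading determinant
  d$y <- sqrt(0.087 / (1 - 0.087)) * d$strong + rnorm(n)
  sel <- cross_validated_selection(d, "y", names(d)[names(d) != "y"],
                                   n_iter = 60, seed = 5)
  tab <- tidy(sel)
  expect_gte(tab$frequency[tab$candidate == "strong"], 0.70)
  expect_true("strong" %in% sel$retained)
  expect_true(all(tab$frequency[tab$candidate != "strong"] < 0.70))
})

test_that("selection report satisfies its count invariants", {
  d <- null_panel_data(300, 6, seed = 3)
  d$y <- 0.4 * d$c01 + d$y
  sel <- cross_validated_selection(d, "y", sprintf("c%02d", 1:6),
                                   n_iter = 40, seed = 9)
  tab <- tidy(sel)
  expect_true(all(tab$validated_count <= tab$selected_count))
  expect_true(all(tab$selected_count <= sel$n_iter))
  expect_true(all(sel$retained %in% tab$candidate))
  expect_equal(tab$frequency, tab$validated_count / sel$n_iter)
  g <- glance(sel)
  expect_equal(g$n_iter, 40)
  expect_equal(g$n_retained, length(sel$retained))
})

test_that("threshold 0 retains every ever-validated candidate", {
  d <- null_panel_data(300, 5, seed = 4)
  d$y <- 0.5 * d$c01 + d$y
  sel <- cross_validated_selection(d, "y", sprintf("c%02d", 1:5),
                                   n_iter = 30, threshold = 0, seed = 2)
  tab <- tidy(sel)
  expect_setequal(sel$retained, tab$candidate[tab$validated_count > 0])
})

test_that("the split sequence reproduces from the master seed", {
  d <- null_panel_data(200, 4, seed = 5)
  d$y <- 0.6 * d$c01 + d$y
  a <- cross_validated_selection(d, "y", sprintf("c%02d", 1:4),
                                 n_iter = 15, seed = 11)
  b <- cross_validated_selection(d, "y", sprintf("c%02d", 1:4),
                                 n_iter = 15, seed = 11)
  expect_identical(a$iterations, b$iterations)
  expect_identical(tidy(a), tidy(b))
  c2 <- cross_validated_selection(d, "y", sprintf("c%02d", 1:4),
                                  n_iter = 15, seed = 12)
  expect_false(identical(a$iterations, c2$iterations))
})

test_that("selection frequencies are invariant to candidate ordering", {
  d <- null_panel_data(400, 6, seed = 6)
  d$y <- 0.5 * d$c01 - 0.3 * d$c02 + d$y
  cands <- sprintf("c%02d", 1:6)
  a <- cross_validated_selection(d, "y", cands, n_iter = 20, seed = 3)
  b <- cross_validated_selection(d, "y", rev(cands), n_iter = 20, seed = 3)
  ta <- dplyr::arrange(tidy(a), candidate)
  tb <- dplyr::arrange(tidy(b), candidate)
  expect_equal(ta$frequency, tb$frequency)
  expect_setequal(a$retained, b$retained)
})

test_that("whole-model validation variant runs and validates jointly", {
  d <- null_panel_data(300, 4, seed = 7)
  d$y <- 0.7 * d$c01 + d$y
  sel <- cross_validated_selection(d, "y", sprintf("c%02d", 1:4),
                                   n_iter = 20, validate = "model", seed = 4)
  tab <- tidy(sel)
  expect_true("c01" %in% sel$retained)
  expect_true(all(tab$validated_count <= tab$selected_count))
})
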