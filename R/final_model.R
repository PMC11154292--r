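#' Final multiple-regression model with partial R-squared decomposition
#'
#' Fits the multiple linear regression of a GSM outcome on the retained
#' predictors (complete cases; every predictor standardized to unit sample
#' SD, quartile-coded predictors entered as ordinal 1-4 before
#' standardization), so coefficients are semi-standardized: outcome units
#' per predictor SD. The per-predictor partial R-squared is the sequential
#' incremental R-squared with predictors entered in order of decreasing
#' contribution (greedy), which makes the components additive: they sum to
#' the whole-model R-squared. Squared partial correlations are reported as
#' a secondary column.
#'
#' @param data Tibble with the outcome and predictor columns.
#' @param outcome Outcome column name (adjusted GSM).
#' @param predictors Character vector of retained predictor columns.
#' @return A `gsm_fit` object.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 600, seed = 2))
#' cohort <- adjust_cohort_gsm(cohort)
#' fit <- fit_final_model(cohort, "im_gsm", c("latitude", "height", "sbp"))
#' glance(fit)
fit_final_model <- function(data, outcome, predictors) {
  stopifnot(length(predictors) >= 1, outcome %in% names(data),
            all(predictors %in% names(data)))
  df <- as.data.frame(data[c(outcome, predictors)])
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n < 10 * length(predictors)) {
    stop("need at least 10 complete cases per predictor", call. = FALSE)
  }
  y <- df[[outcome]]
  Z <- standardize_cols(df[predictors])
  qrz <- qr(cbind(1, Z))
  if (qrz$rank < ncol(Z) + 1) {
    aliased <- predictors[qrz$pivot[-seq_len(qrz$rank)] - 1L]
    stop("rank-deficient design; collinear set involves: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  zdf <- data.frame(y = y, Z)
  names(zdf) <- c(".y", predictors)
  fit <- lm(.y ~ ., data = zdf)
  sm <- summary(fit)
  r2 <- sm$r.squared

  # greedy sequential decomposition: at each step enter the predictor with
  # the largest incremental R-squared
  r2_of <- function(vars) {
    if (length(vars) == 0) return(0)
    summary(lm(.y ~ ., data = zdf[c(".y", vars)]))$r.squared
  }
  order_sel <- character(0)
  gains <- numeric(0)
  current <- 0
  remaining <- predictors
  while (length(remaining) > 0) {
    cand_r2 <- vapply(remaining, function(v) r2_of(c(order_sel, v)), numeric(1))
    best <- which.max(cand_r2)
    gains <- c(gains, cand_r2[best] - current)
    current <- cand_r2[best]
    order_sel <- c(order_sel, remaining[best])
    remaining <- remaining[-best]
  }
  partial_r2 <- setNames(gains, order_sel)[predictors]

  ct <- sm$coefficients[-1, , drop = FALSE]
  dfres <- fit$df.residual
  tvals <- ct[, "t value"]
  partial_cor2 <- tvals^2 / (tvals^2 + dfres)

  terms_tab <- tibble::tibble(
    term = predictors,
    estimate = unname(ct[predictors, "Estimate"]),
    std_error = unname(ct[predictors, "Std. Error"]),
    statistic = unname(ct[predictors, "t value"]),
    p_value = unname(ct[predictors, "Pr(>|t|)"]),
    partial_r2 = unname(partial_r2),
    partial_cor2 = unname(partial_cor2[predictors])
  ) |> dplyr::arrange(dplyr::desc(.data$partial_r2))

  structure(
    list(terms = terms_tab, r_squared = r2,
         adj_r_squared = sm$adj.r.squared, sigma = sm$sigma,
         n_used = n, outcome = outcome, entry_order = order_sel,
         lm_fit = fit),
    class = "gsm_fit"
  )
}

#' @export
print.gsm_fit <- function(x, ...) {
  cat("<gsm_fit> outcome:", x$outcome, "| n =", x$n_used,
      "| R^2 =", sprintf("%.3f", x$r_squared), "\n")
  print(x$terms)
  invisible(x)
}

#' @describeIn fit_final_model Per-predictor semi-standardized estimates,
#'   p-values and partial R-squared as a tibble.
#' @param x A `gsm_fit` object.
#' @param ... Unused.
#' @method tidy gsm_fit
#' @export
tidy.gsm_fit <- function(x, ...) x$terms

#' @describeIn fit_final_model One-row model summary (whole-model
#'   R-squared, residual SD, n).
#' @method glance gsm_fit
#' @export
glance.gsm_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, r_squared = x$r_squared,
    adj_r_squared = x$adj_r_squared, sigma = x$sigma, n_used = x$n_used
  )
}

#' @describeIn fit_final_model Bar chart of the partial R-squared
#'   decomposition.
#' @param object A `gsm_fit` object.
#' @method autoplot gsm_fit
#' @export
autoplot.gsm_fit <- function(object, ...) {
  d <- object$terms
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$term, .data$partial_r2),
    y = 100 * .data$partial_r2
  )) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "partial R² (%)",
      title = paste("Variance decomposition:", object$outcome),
      subtitle = sprintf("whole model R² = %.1f%%", 100 * object$r_squared)
    ) +
    ggplot2::theme_minimal()
}
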