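#' Pearson correlation between plaque-GSM and IM-GSM
#'
#' @param data Tibble with the two GSM columns.
#' @param plaque,im Column names (defaults `plaque_gsm`, `im_gsm`).
#' @return One-row tibble with `r`, `p_value`, `conf_low`, `conf_high`, `n`.
#' @export
#' @examples
#' d <- tibble::tibble(plaque_gsm = rnorm(50))
#' d$im_gsm <- d$plaque_gsm + rnorm(50)
#' correlate_gsm(d)
correlate_gsm <- function(data, plaque = "plaque_gsm", im = "im_gsm") {
  x <- data[[plaque]]; y <- data[[im]]
  ok <- complete.cases(x, y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate), p_value = ct$p.value,
    conf_low = ct$conf.int[1], conf_high = ct$conf.int[2],
    n = sum(ok)
  )
}

# Standard adjustment covariates of the burden models.
burden_covariates <- function() {
  c("latitude", "sex_male", "age", "educational_level",
    "pulse_pressure", "pack_years_code")
}

# Restrict to rows with both GSM measures and thickness; compute the
# within-sample quartile codes and the high-burden indicator (IMT_max in
# the upper quartile of the analysis sample).
burden_frame <- function(data, covariates) {
  need <- c("plaque_gsm", "im_gsm", "imt_max", covariates)
  stopifnot(all(need %in% names(data)))
  d <- data[complete.cases(as.data.frame(data[need])), need]
  d$plaque_q <- quartile_code(d$plaque_gsm)
  d$im_q <- quartile_code(d$im_gsm)
  d$high_burden <- as.integer(d$imt_max >= quantile(d$imt_max, 0.75, type = 7))
  d
}

#' Adjusted odds ratio for high burden per GSM quartile increase
#'
#' Logistic regression of high atherosclerotic burden (maximum intima-media
#' thickness in the upper quartile of the analysis sample) on one GSM
#' quartile entered as ordinal 1-4, adjusted for latitude, sex, age,
#' educational level, pulse pressure and the pack-years code. The analysis
#' sample is the subjects with both GSM measures.
#'
#' @param data Tibble with adjusted GSM columns (`plaque_gsm`, `im_gsm`),
#'   `imt_max` and the adjustment covariates.
#' @param which `"plaque"` or `"im"`.
#' @param covariates Adjustment covariate columns.
#' @return One-row tibble with `which`, `or`, `conf_low`, `conf_high`
#'   (Wald 95% CI), `p_value`, `n`.
#' @export
or_per_quartile <- function(data, which = c("plaque", "im"),
                            covariates = burden_covariates()) {
  which <- match.arg(which)
  d <- burden_frame(data, covariates)
  d$gsm_q <- if (which == "plaque") d$plaque_q else d$im_q
  fml <- stats::reformulate(c("gsm_q", covariates), response = "high_burden")
  fit <- glm(fml, data = d, family = binomial())
  ct <- summary(fit)$coefficients["gsm_q", ]
  tibble::tibble(
    which = which,
    or = exp(ct[["Estimate"]]),
    conf_low = exp(ct[["Estimate"]] - 1.96 * ct[["Std. Error"]]),
    conf_high = exp(ct[["Estimate"]] + 1.96 * ct[["Std. Error"]]),
    p_value = ct[["Pr(>|z|)"]],
    n = nrow(d)
  )
}

#' Quartile-by-quartile odds-ratio grid for high atherosclerotic burden
#'
#' One logistic model with 15 indicator terms for the plaque-GSM x IM-GSM
#' quartile cells (the reference cell — plaque-GSM Q4, IM-GSM Q1 — omitted)
#' plus the adjustment covariates. A supplementary quadratic-term p-value
#' for the IM-GSM quartile (testing curvature of the burden relationship)
#' is included as descriptive output.
#'
#' @inheritParams or_per_quartile
#' @param reference Length-2 integer `c(plaque_q, im_q)` of the reference
#'   cell (default `c(4, 1)`).
#' @return A `gsm_or_grid` object; `tidy()` gives the long cell table.
#' @export
or_grid <- function(data, covariates = burden_covariates(),
                    reference = c(4L, 1L)) {
  d <- burden_frame(data, covariates)
  cell <- interaction(d$plaque_q, d$im_q, sep = ":")
  ref_lab <- paste(reference[1], reference[2], sep = ":")
  if (!ref_lab %in% levels(cell)) stop("reference cell is empty", call. = FALSE)
  cell <- stats::relevel(cell, ref = ref_lab)
  d$cell <- cell
  fml <- stats::reformulate(c("cell", covariates), response = "high_burden")
  fit <- glm(fml, data = d, family = binomial())
  cf <- summary(fit)$coefficients
  lv <- levels(cell)
  grid <- tidyr::expand_grid(plaque_q = 1:4, im_q = 1:4)
  grid$n <- as.integer(table(factor(paste(d$plaque_q, d$im_q, sep = ":"),
                                    levels = paste(grid$plaque_q, grid$im_q,
                                                   sep = ":"))))
  get_row <- function(pq, iq) {
    lab <- paste(pq, iq, sep = ":")
    if (lab == ref_lab) return(c(1, 1, 1, NA))
    nm <- paste0("cell", lab)
    if (!nm %in% rownames(cf)) return(c(NA, NA, NA, NA))
    est <- cf[nm, "Estimate"]; se <- cf[nm, "Std. Error"]
    c(exp(est), exp(est - 1.96 * se), exp(est + 1.96 * se),
      cf[nm, "Pr(>|z|)"])
  }
  vals <- t(mapply(get_row, grid$plaque_q, grid$im_q))
  grid$or <- vals[, 1]; grid$conf_low <- vals[, 2]
  grid$conf_high <- vals[, 3]; grid$p_value <- vals[, 4]
  grid$reference <- grid$plaque_q == reference[1] & grid$im_q == reference[2]
  empty <- grid$n == 0
  if (any(empty)) {
    message("empty OR-grid cells: ",
            paste(paste0("(", grid$plaque_q[empty], ",", grid$im_q[empty], ")"),
                  collapse = " "))
  }
  quad_fit <- glm(
    stats::reformulate(c("im_q", "I(im_q^2)", covariates),
                       response = "high_burden"),
    data = d, family = binomial()
  )
  quad_p <- summary(quad_fit)$coefficients["I(im_q^2)", "Pr(>|z|)"]
  structure(
    list(grid = grid, reference = reference, n = nrow(d),
         covariates = covariates, im_quadratic_p = unname(quad_p),
         glm_fit = fit),
    class = "gsm_or_grid"
  )
}

#' @export
print.gsm_or_grid <- function(x, ...) {
  cat("<gsm_or_grid> n =", x$n, "| reference cell: plaque Q",
      x$reference[1], ", IM Q", x$reference[2], "\n")
  wide <- tidyr::pivot_wider(x$grid[c("plaque_q", "im_q", "or")],
                             names_from = "im_q", values_from = "or",
                             names_prefix = "imQ")
  print(wide)
  cat(sprintf("supplementary IM quadratic-term p = %.3g\n", x$im_quadratic_p))
  invisible(x)
}

#' @describeIn or_grid Long cell table with ORs and CIs.
#' @param x A `gsm_or_grid` object.
#' @param ... Unused.
#' @method tidy gsm_or_grid
#' @export
tidy.gsm_or_grid <- function(x, ...) x$grid

#' @describeIn or_grid Grouped bar chart of the OR grid.
#' @param object A `gsm_or_grid` object.
#' @method autoplot gsm_or_grid
#' @export
autoplot.gsm_or_grid <- function(object, ...) {
  d <- object$grid
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$plaque_q), y = .data$or,
    fill = factor(.data$im_q)
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_fill_brewer(palette = "Blues", name = "IM-GSM quartile") +
    ggplot2::labs(
      x = "plaque-GSM quartile",
      y = "OR for high atherosclerotic burden",
      title = "Burden odds by echolucency quartiles",
      subtitle = sprintf("reference: plaque Q%d, IM Q%d; n = %d",
                         object$reference[1], object$reference[2], object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Dichotomized-GSM prediction and AUC comparison
#'
#' Dichotomizes each GSM outcome at its median, fits a logistic model of
#' the above-median indicator on the retained predictors, and reports each
#' model's ROC AUC with a DeLong 95% CI. Because the two dichotomized
#' outcomes are different responses measured on the same subjects, the AUC
#' difference is tested by a subject-level bootstrap of the paired AUC
#' difference on the common subject set.
#'
#' @param data Tibble with both GSM columns and the predictors.
#' @param predictors_plaque,predictors_im Predictor sets for the two
#'   models (defaults: the determinant sets of the two outcome models).
#' @param n_boot Bootstrap replicates for the difference test (default 2000).
#' @param seed Seed for the bootstrap.
#' @return A `gsm_auc` object; `tidy()` gives one row per outcome.
#' @export
predict_dichotomized_gsm <- function(data,
                                     predictors_plaque = effect_table_plaque()$predictor,
                                     predictors_im = effect_table_im()$predictor,
                                     n_boot = 2000L, seed = 1L) {
  fit_one <- function(outcome, predictors) {
    d <- as.data.frame(data[c(outcome, predictors)])
    ok <- complete.cases(d)
    d <- d[ok, , drop = FALSE]
    med <- median(d[[outcome]])
    d$.above <- as.integer(d[[outcome]] > med)
    fml <- stats::reformulate(predictors, response = ".above")
    fit <- tryCatch(
      glm(fml, data = d, family = binomial()),
      warning = function(w) {
        # separation etc.: refit with slight ridge via glm control fallback
        suppressWarnings(glm(fml, data = d, family = binomial(),
                             control = list(maxit = 100)))
      }
    )
    score <- predict(fit, type = "link")
    roc <- pROC::roc(d$.above, score, quiet = TRUE, direction = "<")
    ci <- as.numeric(pROC::ci.auc(roc, method = "delong"))
    list(rows = ok, above = d$.above, score = score,
         auc = as.numeric(pROC::auc(roc)), ci = ci[c(1, 3)], n = nrow(d))
  }
  mp <- fit_one("plaque_gsm", predictors_plaque)
  mi <- fit_one("im_gsm", predictors_im)

  # paired bootstrap of the AUC difference on the common subjects
  common <- which(mp$rows & mi$rows)
  ip <- match(common, which(mp$rows))
  ii <- match(common, which(mi$rows))
  set.seed(seed)
  nb <- length(common)
  diffs <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nb, replace = TRUE)
    rank_auc(mi$score[ii][idx], mi$above[ii][idx]) -
      rank_auc(mp$score[ip][idx], mp$above[ip][idx])
  }, numeric(1))
  diffs <- diffs[is.finite(diffs)]
  d_obs <- rank_auc(mi$score[ii], mi$above[ii]) -
    rank_auc(mp$score[ip], mp$above[ip])
  zstat <- d_obs / sd(diffs)
  p_diff <- 2 * stats::pnorm(abs(zstat), lower.tail = FALSE)

  structure(
    list(
      table = tibble::tibble(
        outcome = c("plaque_gsm", "im_gsm"),
        auc = c(mp$auc, mi$auc),
        conf_low = c(mp$ci[1], mi$ci[1]),
        conf_high = c(mp$ci[2], mi$ci[2]),
        n = c(mp$n, mi$n)
      ),
      auc_plaque = mp$auc, auc_im = mi$auc,
      difference = d_obs, p_difference = p_diff,
      n_common = nb, n_boot = length(diffs)
    ),
    class = "gsm_auc"
  )
}

#' @export
print.gsm_auc <- function(x, ...) {
  cat("<gsm_auc> AUC plaque", sprintf("%.3f", x$auc_plaque),
      "| AUC IM", sprintf("%.3f", x$auc_im),
      "| paired-bootstrap p =", format.pval(x$p_difference, digits = 3), "\n")
  print(x$table)
  invisible(x)
}

#' @describeIn predict_dichotomized_gsm Per-outcome AUC table.
#' @param x A `gsm_auc` object.
#' @param ... Unused.
#' @method tidy gsm_auc
#' @export
tidy.gsm_auc <- function(x, ...) x$table

#' @describeIn predict_dichotomized_gsm One-row comparison summary.
#' @method glance gsm_auc
#' @export
glance.gsm_auc <- function(x, ...) {
  tibble::tibble(
    auc_plaque = x$auc_plaque, auc_im = x$auc_im,
    difference = x$difference, p_difference = x$p_difference,
    n_common = x$n_common
  )
}
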