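#' Default candidate panel for a GSM outcome
#'
#' Lists the analysis columns screened as candidate determinants of the
#' given outcome, with their declared distribution type (which picks the
#' univariate test) and the transform already applied to the column.
#' Nuisance columns present in `data` (named `nuisNN`) are appended as
#' normal candidates, emulating the wider screened covariate panel.
#'
#' @param outcome `"plaque_gsm"` or `"im_gsm"`.
#' @param data Optional cohort tibble used to pick up nuisance columns.
#' @return Tibble with `candidate`, `type`
#'   (`"normal"`, `"skewed"`, `"binary"`) and `transform`.
#' @export
candidate_panel <- function(outcome = c("plaque_gsm", "im_gsm"), data = NULL) {
  outcome <- match.arg(outcome)
  base <- tibble::tribble(
    ~candidate,          ~type,     ~transform,
    "latitude",          "normal",  "identity",
    "age",               "normal",  "identity",
    "sex_male",          "binary",  "identity",
    "height",            "normal",  "identity",
    "waist_hip_ratio",   "normal",  "identity",
    "sbp",               "normal",  "identity",
    "dbp",               "normal",  "identity",
    "pack_years_code",   "normal",  "tertile-code",
    "educational_level", "normal",  "identity",
    "creatinine_log",    "skewed",  "log",
    "mcv",               "normal",  "identity",
    "fibrates",          "binary",  "identity",
    "sartans",           "binary",  "identity"
  )
  thick <- if (outcome == "plaque_gsm") {
    tibble::tibble(candidate = "imt_max_q", type = "normal",
                   transform = "quartile-code")
  } else {
    tibble::tibble(candidate = "pf_cc_imt_q", type = "normal",
                   transform = "quartile-code")
  }
  panel <- dplyr::bind_rows(base, thick)
  if (!is.null(data)) {
    nn <- grep("^nuis[0-9]+$", names(data), value = TRUE)
    if (length(nn)) {
      panel <- dplyr::bind_rows(
        panel,
        tibble::tibble(candidate = nn, type = "normal", transform = "identity")
      )
    }
  }
  stopifnot(!anyDuplicated(panel$candidate))
  panel
}

#' Univariate screen of candidate determinants across GSM quartiles
#'
#' Stratifies the outcome into quartiles and tests each candidate for group
#' differences with the test matching its declared type: one-way ANOVA
#' (with a Bonferroni pairwise post hoc) for normal numeric candidates,
#' Kruskal-Wallis for skewed ones, and a chi-squared test — or Fisher's
#' exact test when any expected cell count is below 5 — for binary or
#' categorical ones. A semi-standardized trend beta (outcome units per
#' candidate SD) is reported for numeric candidates. The significance flag
#' uses a Bonferroni-corrected threshold for the size of the screened panel
#' (0.05 / 73 rounded to 0.0007 at the default panel size).
#'
#' @param data Tibble containing the outcome and candidate columns.
#' @param outcome Name of the outcome column (adjusted GSM).
#' @param panel Candidate panel tibble, see [candidate_panel()].
#' @param alpha Familywise significance threshold (default 0.0007).
#' @return Tibble with one row per candidate: `candidate`, `type`, `test`,
#'   `statistic`, `p_value`, `posthoc_min_p`, `trend_beta`, `significant`.
#' @export
univariate_screen <- function(data, outcome, panel = NULL, alpha = 0.0007) {
  if (is.null(panel)) {
    panel <- candidate_panel(match.arg(outcome, c("plaque_gsm", "im_gsm")),
                             data = data)
  }
  stopifnot(outcome %in% names(data), !anyDuplicated(panel$candidate))
  y <- data[[outcome]]
  grp <- factor(quartile_code(y))
  if (nlevels(grp) < 2) stop("outcome quartiles are not computable", call. = FALSE)

  one <- function(cand, type) {
    x <- data[[cand]]
    ok <- !is.na(x) & !is.na(y)
    if (!any(ok)) {
      return(tibble::tibble(candidate = cand, type = type, test = "none",
                            statistic = NA_real_, p_value = NA_real_,
                            posthoc_min_p = NA_real_, trend_beta = NA_real_,
                            significant = NA))
    }
    xo <- x[ok]; go <- droplevels(grp[ok]); yo <- y[ok]
    test <- statistic <- pval <- posthoc <- beta <- NA
    if (type == "normal") {
      fit <- aov(xo ~ go)
      a <- summary(fit)[[1]]
      statistic <- a[["F value"]][1]
      pval <- a[["Pr(>F)"]][1]
      ph <- suppressWarnings(
        stats::pairwise.t.test(xo, go, p.adjust.method = "bonferroni")
      )
      posthoc <- suppressWarnings(min(ph$p.value, na.rm = TRUE))
      test <- "anova"
    } else if (type == "skewed") {
      k <- kruskal.test(xo, go)
      statistic <- unname(k$statistic)
      pval <- k$p.value
      test <- "kruskal-wallis"
    } else {
      tab <- table(xo, go)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        f <- fisher.test(tab, simulate.p.value = length(tab) > 10,
                         B = 10000)
        pval <- f$p.value
        test <- "fisher"
      } else {
        cs <- suppressWarnings(chisq.test(tab))
        statistic <- unname(cs$statistic)
        pval <- cs$p.value
        test <- "chi-squared"
      }
    }
    if (is.numeric(xo) && sd(xo) > 0) {
      beta <- unname(coef(lm(yo ~ scale(xo)))[2])
    }
    tibble::tibble(candidate = cand, type = type, test = test,
                   statistic = as.numeric(statistic),
                   p_value = as.numeric(pval),
                   posthoc_min_p = as.numeric(posthoc),
                   trend_beta = as.numeric(beta),
                   significant = !is.na(pval) & pval < alpha)
  }
  purrr::map2_dfr(panel$candidate, panel$type, one)
}
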