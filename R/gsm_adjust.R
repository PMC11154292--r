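#' A priori adjustment of GSM for the calibration references
#'
#' Despite per-image recalibration, the reference black and white levels can
#' remain confounders of GSM. This removes their linear footprint: GSM is
#' regressed on black and white (with intercept) and the residuals are
#' re-centered to the original grand mean, so the output is uncorrelated
#' with both references and preserves the mean exactly.
#'
#' @param gsm Numeric vector of GSM values (`NA` allowed; preserved).
#' @param black,white Numeric vectors of per-image reference levels, same
#'   length as `gsm`.
#' @return Adjusted GSM vector.
#' @export
#' @examples
#' black <- rep(0:37, length.out = 50)
#' white <- rep(104:255, length.out = 50)
#' gsm <- 30 + 2 * black + rnorm(50)
#' adj <- adjust_for_calibration(gsm, black, white)
#' cor(adj, black)
adjust_for_calibration <- function(gsm, black, white) {
  stopifnot(length(gsm) == length(black), length(gsm) == length(white))
  ok <- complete.cases(gsm, black, white)
  if (sum(ok) < 3) stop("need at least 3 complete observations", call. = FALSE)
  if (sd(black[ok]) == 0 && sd(white[ok]) == 0) {
    warning("constant black and white references: GSM returned unchanged")
    return(gsm)
  }
  fit <- lm(gsm ~ black + white, na.action = na.exclude)
  residuals(fit) + mean(gsm, na.rm = TRUE)
}

#' Scan-rescan reproducibility statistics
#'
#' Mean and SD of the absolute scan difference, plus the one-way
#' random-effects single-measure intraclass correlation
#' `(MSB - MSW) / (MSB + MSW)` for two scans per subject.
#'
#' @param pairs Tibble with columns `scan1` and `scan2`.
#' @return One-row tibble with `n`, `mean_abs_diff`, `sd_abs_diff`, `icc`.
#' @export
#' @examples
#' reproducibility_stats(tibble::tibble(scan1 = c(1, 5), scan2 = c(3, 9)))
reproducibility_stats <- function(pairs) {
  stopifnot(all(c("scan1", "scan2") %in% names(pairs)))
  ok <- complete.cases(pairs$scan1, pairs$scan2)
  y1 <- pairs$scan1[ok]; y2 <- pairs$scan2[ok]
  n <- length(y1)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- y1 - y2
  m <- (y1 + y2) / 2
  msw <- sum(d^2 / 2) / n
  msb <- 2 * sum((m - mean(m))^2) / (n - 1)
  tibble::tibble(
    n = n,
    mean_abs_diff = mean(abs(d)),
    sd_abs_diff = sd(abs(d)),
    icc = (msb - msw) / (msb + msw)
  )
}
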