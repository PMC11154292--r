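#' Quartile-code a numeric vector
#'
#' Assigns codes 1-4 by the sample quartiles of `x`. Boundaries are the
#' type-7 quantiles of the analysis sample; values equal to a boundary go to
#' the lower quartile (ties-to-lower).
#'
#' @param x Numeric vector.
#' @param breaks Optional length-3 vector of cut points (25th, 50th, 75th
#'   percentiles). Computed from `x` when `NULL`.
#' @return Integer vector of codes in `1:4` (`NA` preserved).
#' @export
#' @examples
#' quartile_code(1:8)
quartile_code <- function(x, breaks = NULL) {
  stopifnot(is.numeric(x))
  if (is.null(breaks)) {
    breaks <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  }
  stopifnot(length(breaks) == 3L)
  out <- findInterval(x, breaks, left.open = TRUE) + 1L
  out[is.na(x)] <- NA_integer_
  out
}

# Draw n reproducible sub-seeds from a master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

# Standardize columns of a matrix/data.frame by sample mean and sd.
# Columns with zero sd are left centered at 0.
standardize_cols <- function(m) {
  m <- as.matrix(m)
  mu <- colMeans(m, na.rm = TRUE)
  s <- apply(m, 2, sd, na.rm = TRUE)
  s[!is.finite(s) | s == 0] <- 1
  sweep(sweep(m, 2, mu, "-"), 2, s, "/")
}

# OLS coefficient two-sided p-values for design X (with intercept column)
# and response y. Returns the p-value vector aligned with columns of X;
# aliased columns get NA.
ols_pvalues <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  r <- fit$rank
  df <- length(y) - r
  if (df <= 0) return(rep(NA_real_, ncol(X)))
  piv <- fit$qr$pivot[seq_len(r)]
  Rinv <- chol2inv(fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE])
  s2 <- sum(fit$residuals^2) / df
  se <- rep(NA_real_, ncol(X))
  se[piv] <- sqrt(pmax(diag(Rinv), 0) * s2)
  tval <- fit$coefficients / se
  2 * pt(abs(tval), df, lower.tail = FALSE)
}

# Rank-based empirical AUC of score for binary outcome (1 = positive).
rank_auc <- function(score, outcome) {
  pos <- outcome == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
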