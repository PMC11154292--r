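#' Forward-stepwise predictor selection with backward pruning
#'
#' Forward-stepwise linear regression: at each step the candidate with the
#' smallest partial F-test p-value enters if it is below `entry_p`; any
#' included predictor whose coefficient p-value rises above `stay_p` is then
#' dropped (worst first). Iterates to a fixed point and is deterministic
#' given the data (exact p-value ties resolve to the earlier candidate in
#' `candidates`). Candidates whose residual variance after projection on the
#' current model falls below `cond_tol` of their total variance are skipped
#' as collinear and recorded in the `skipped` attribute.
#'
#' The scan is computed by QR residualization (partial correlations of the
#' candidates with the current model residual), which is algebraically the
#' single-term-addition F test.
#'
#' @param data Tibble with the outcome and candidate columns.
#' @param outcome Outcome column name.
#' @param candidates Character vector of candidate column names.
#' @param entry_p Entry threshold (default 0.05).
#' @param stay_p Stay threshold (default 0.10).
#' @param cond_tol Relative residual-variance floor below which a candidate
#'   is treated as collinear (default 1e-8).
#' @return Character vector of selected candidates (possibly empty), with
#'   attribute `skipped` listing collinear candidates that were skipped.
#' @export
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(x1 = rnorm(300), x2 = rnorm(300))
#' d$y <- 0.8 * d$x1 + rnorm(300)
#' stepwise_select(d, "y", c("x1", "x2"))
stepwise_select <- function(data, outcome, candidates,
                            entry_p = 0.05, stay_p = 0.10, cond_tol = 1e-8) {
  stopifnot(outcome %in% names(data), length(candidates) >= 1,
            all(candidates %in% names(data)),
            entry_p >= 0, stay_p >= entry_p)
  C <- as.matrix(data[candidates])
  storage.mode(C) <- "double"
  y <- as.numeric(data[[outcome]])
  keep <- complete.cases(C, y)
  C <- C[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y)
  if (n <= length(candidates) + 2) {
    stop("not enough complete rows for the candidate panel", call. = FALSE)
  }
  ctss <- colSums(sweep(C, 2, colMeans(C))^2)

  included <- character(0)
  skipped <- character(0)
  seen <- character(0)
  repeat {
    state <- paste(sort(included), collapse = "|")
    if (state %in% seen) break  # cycle guard
    seen <- c(seen, state)
    changed <- FALSE

    # forward step
    rem <- setdiff(candidates, included)
    if (length(rem) > 0 && n > length(included) + 2) {
      X <- cbind(1, C[, included, drop = FALSE])
      qx <- qr(X)
      Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
      ry <- y - Q %*% crossprod(Q, y)
      ryss <- sum(ry^2)
      Crem <- C[, rem, drop = FALSE]
      E <- Crem - Q %*% crossprod(Q, Crem)
      ess <- colSums(E^2)
      ok <- ess > cond_tol * pmax(ctss[rem], .Machine$double.eps)
      skipped <- union(skipped, rem[!ok])
      if (any(ok) && ryss > 0) {
        num <- as.vector(crossprod(E[, ok, drop = FALSE], ry))
        r2 <- num^2 / (ess[ok] * ryss)
        dfree <- n - qx$rank - 1
        tstat <- sqrt(pmin(pmax(r2, 0), 1 - 1e-12) * dfree /
                        pmax(1 - r2, 1e-12))
        pvals <- 2 * pt(tstat, dfree, lower.tail = FALSE)
        best <- which.min(pvals)
        if (pvals[best] < entry_p) {
          included <- c(included, rem[ok][best])
          changed <- TRUE
        }
      }
    }

    # backward step
    if (length(included) > 0) {
      X <- cbind(1, C[, included, drop = FALSE])
      pv <- ols_pvalues(X, y)[-1]
      pv[is.na(pv)] <- Inf  # aliased -> drop
      worst <- which.max(pv)
      if (pv[worst] > stay_p) {
        included <- included[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(included, skipped = skipped)
}

#' Split-sample stability selection of GSM determinants
#'
#' Repeats, for `n_iter` random half-splits of the data: stepwise selection
#' on the training half, then a refit of the selected model on the testing
#' half. A candidate counts as *validated* in an iteration iff it was
#' selected and its testing-half coefficient has p < `validate_p`. The
#' retained set contains the candidates whose validated frequency reaches
#' `threshold`. Iteration split seeds derive from the master `seed`, so the
#' whole procedure is reproducible and invariant to candidate ordering (up
#' to exact-tie breaking inside the stepwise scan).
#'
#' @param data Tibble with the outcome and candidate columns.
#' @param outcome Outcome column name.
#' @param candidates Character vector of candidate columns.
#' @param n_iter Number of half-split iterations (default 200).
#' @param threshold Retention frequency threshold (default 0.70).
#' @param entry_p,stay_p Stepwise thresholds, see [stepwise_select()].
#' @param validate_p Testing-half per-coefficient significance level
#'   (default 0.05). Set `validate` to `"model"` to instead validate all
#'   selected candidates when the testing-half whole-model F-test has
#'   p < `validate_p`.
#' @param validate `"coefficient"` (default) or `"model"`.
#' @param seed Master seed for the split sequence.
#' @return A `gsm_selection` object: per-candidate counts and frequencies,
#'   the retained set, and the per-iteration selection log.
#' @export
cross_validated_selection <- function(data, outcome, candidates,
                                      n_iter = 200L, threshold = 0.70,
                                      entry_p = 0.05, stay_p = 0.10,
                                      validate_p = 0.05,
                                      validate = c("coefficient", "model"),
                                      seed = 1L) {
  validate <- match.arg(validate)
  stopifnot(n_iter >= 1, threshold >= 0, threshold <= 1,
            length(candidates) >= 1)
  C <- as.matrix(data[candidates])
  storage.mode(C) <- "double"
  y <- as.numeric(data[[outcome]])
  keep <- complete.cases(C, y)
  C <- C[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y)
  if (n < 40) stop("need at least 40 complete rows", call. = FALSE)

  it_seeds <- derive_seeds(seed, n_iter)
  selected_count <- validated_count <- setNames(integer(length(candidates)),
                                                candidates)
  sel_log <- vector("list", n_iter)
  df_tr <- tibble::as_tibble(as.data.frame(C))
  df_tr[[outcome]] <- y
  for (i in seq_len(n_iter)) {
    set.seed(it_seeds[i])
    perm <- sample.int(n)
    train <- perm[seq_len(floor(n / 2))]
    test <- perm[(floor(n / 2) + 1):n]
    sel <- tryCatch(
      stepwise_select(df_tr[train, , drop = FALSE], outcome, candidates,
                      entry_p = entry_p, stay_p = stay_p),
      error = function(e) character(0)
    )
    sel_log[[i]] <- sel
    if (length(sel) == 0) next
    selected_count[sel] <- selected_count[sel] + 1L
    Xt <- cbind(1, C[test, sel, drop = FALSE])
    yt <- y[test]
    if (validate == "coefficient") {
      pv <- ols_pvalues(Xt, yt)[-1]
      good <- sel[!is.na(pv) & pv < validate_p]
    } else {
      ft <- stats::lm.fit(Xt, yt)
      rss <- sum(ft$residuals^2)
      tss <- sum((yt - mean(yt))^2)
      k <- ft$rank - 1
      dfres <- length(yt) - ft$rank
      fstat <- ((tss - rss) / k) / (rss / dfres)
      pmod <- stats::pf(fstat, k, dfres, lower.tail = FALSE)
      good <- if (!is.na(pmod) && pmod < validate_p) sel else character(0)
    }
    validated_count[good] <- validated_count[good] + 1L
  }
  freq <- validated_count / n_iter
  keep_cand <- freq >= threshold & validated_count > 0
  tab <- tibble::tibble(
    candidate = candidates,
    selected_count = as.integer(selected_count),
    validated_count = as.integer(validated_count),
    frequency = unname(freq),
    retained = unname(keep_cand)
  )
  structure(
    list(table = tab,
         retained = candidates[keep_cand],
         n_iter = as.integer(n_iter), threshold = threshold,
         entry_p = entry_p, stay_p = stay_p, validate = validate,
         validate_p = validate_p, seed = as.integer(seed),
         outcome = outcome, n_used = n, iterations = sel_log),
    class = "gsm_selection"
  )
}

#' @export
print.gsm_selection <- function(x, ...) {
  cat("<gsm_selection> outcome:", x$outcome, "|", x$n_iter,
      "half-split iterations | threshold", x$threshold, "\n")
  cat("retained (", length(x$retained), "): ",
      paste(x$retained, collapse = ", "), "\n", sep = "")
  print(dplyr::arrange(x$table, dplyr::desc(.data$frequency)), n = 10)
  invisible(x)
}

#' @describeIn cross_validated_selection Per-candidate counts and validated
#'   frequencies as a tibble.
#' @param x A `gsm_selection` object.
#' @param ... Unused.
#' @method tidy gsm_selection
#' @export
tidy.gsm_selection <- function(x, ...) x$table

#' @describeIn cross_validated_selection One-row summary of the procedure.
#' @method glance gsm_selection
#' @export
glance.gsm_selection <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, n_iter = x$n_iter, threshold = x$threshold,
    n_candidates = nrow(x$table), n_retained = length(x$retained),
    n_used = x$n_used, seed = x$seed
  )
}

#' @describeIn cross_validated_selection Bar chart of validated frequencies
#'   with the retention threshold.
#' @param object A `gsm_selection` object.
#' @param top_n Show at most this many candidates (by frequency).
#' @method autoplot gsm_selection
#' @export
autoplot.gsm_selection <- function(object, top_n = 20, ...) {
  d <- object$table |>
    dplyr::arrange(dplyr::desc(.data$frequency)) |>
    head(top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$candidate, .data$frequency),
    y = .data$frequency, fill = .data$retained
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey70")) +
    ggplot2::labs(
      x = NULL, y = "validated frequency",
      title = paste("Stability selection:", object$outcome),
      subtitle = paste0(object$n_iter, " half-split iterations; threshold ",
                        object$threshold)
    ) +
    ggplot2::theme_minimal()
}
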