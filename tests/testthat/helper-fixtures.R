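# Shared fixtures built in code.

small_config <- function(n = 400, seed = 1, ...) {
  cohort_config(n_subjects = n, seed = seed, ...)
}

small_cohort <- function(n = 400, seed = 1, ...) {
  adjust_cohort_gsm(generate_cohort(small_config(n, seed, ...)))
}

# Null screening data: outcome independent of all candidates.
null_panel_data <- function(n, p, seed) {
  set.seed(seed)
  d <- as.data.frame(matrix(rnorm(n * p), n, p,
                            dimnames = list(NULL, sprintf("c%02d", 1:p))))
  d$y <- rnorm(n)
  tibble::as_tibble(d)
}

# Reference stepwise selection via lm + add1/drop1, used as the slow
# independent oracle for the QR-based implementation.
stepwise_reference <- function(data, outcome, candidates,
                               entry_p = 0.05, stay_p = 0.10) {
  included <- character(0)
  dat <- as.data.frame(data[c(outcome, candidates)])
  dat <- dat[stats::complete.cases(dat), ]
  repeat {
    changed <- FALSE
    rem <- setdiff(candidates, included)
    fml <- stats::reformulate(if (length(included)) included else "1",
                              response = outcome)
    fit <- stats::lm(fml, data = dat)
    if (length(rem)) {
      a1 <- stats::add1(fit, scope = stats::reformulate(c(included, rem)),
                        test = "F")
      pv <- a1[["Pr(>F)"]][-1]
      names(pv) <- rownames(a1)[-1]
      best <- which.min(pv)
      if (length(best) && pv[best] < entry_p) {
        included <- c(included, names(pv)[best])
        changed <- TRUE
      }
    }
    if (length(included)) {
      fit2 <- stats::lm(stats::reformulate(included, response = outcome),
                        data = dat)
      d1 <- stats::drop1(fit2, test = "F")
      pv <- d1[["Pr(>F)"]][-1]
      worst <- which.max(pv)
      if (length(worst) && pv[worst] > stay_p) {
        included <- included[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  included
}
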