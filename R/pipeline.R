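#' Configuration of an end-to-end pipeline run
#'
#' @param cohort A [cohort_config()].
#' @param n_iter,threshold,entry_p,stay_p Stability-selection settings.
#' @param w_target Calibration white anchor (see [calibrate_gsm()]).
#' @param n_repeat Scan-rescan subsample size.
#' @param figures Write PNG figures (default `TRUE`).
#' @param seed Master seed of the run (selection splits, rescans, bootstrap).
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(),
                       n_iter = 200L, threshold = 0.70,
                       entry_p = 0.05, stay_p = 0.10,
                       w_target = 190, n_repeat = 138L,
                       figures = TRUE, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"))
  structure(
    list(cohort = cohort, n_iter = as.integer(n_iter), threshold = threshold,
         entry_p = entry_p, stay_p = stay_p, w_target = w_target,
         n_repeat = as.integer(n_repeat), figures = isTRUE(figures),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Top-level keys override [run_config()] arguments; the optional `cohort`
#' mapping overrides [cohort_config()] arguments (`n_subjects`,
#' `plaque_fraction`, `n_nuisance`, `seed`, `cross_gsm_rho`, ...).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cc <- do.call(cohort_config, y$cohort %||% list())
  y$cohort <- NULL
  do.call(run_config, c(list(cohort = cc), y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

md_table <- function(df, digits = 3) {
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, digits = digits, format = "fg") else as.character(v)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

save_fig <- function(plot, path, width = 7, height = 5) {
  tryCatch({
    suppressMessages(ggplot2::ggsave(path, plot, width = width,
                                     height = height, dpi = 120))
    TRUE
  }, error = function(e) {
    warning("figure not written (", conditionMessage(e), ")")
    FALSE
  })
}

#' Run the full echolucency analysis pipeline
#'
#' Orchestrates simulate -> measure -> adjust -> select -> model ->
#' stratify -> report on a synthetic cohort: writes the cohort CSV with a
#' JSON data dictionary, stability-selection reports and final model fits
#' for both GSM outcomes, the correlation, AUC comparison, per-quartile ORs
#' and OR grid, scan-rescan reproducibility statistics, a Markdown report
#' and a manifest with versions and seeds.
#'
#' @param config A [run_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of the in-memory results; files are written
#'   under `dir`.
#' @export
run_pipeline <- function(config = run_config(), dir = tempfile("echowall_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(dir, "run.log")
  logf <- function(stage, ...) {
    line <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste0(..., collapse = ""))
    cat(line, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logf(name, sprintf("done in %.1fs", proc.time()[["elapsed"]] - t0))
    out
  }
  seeds <- derive_seeds(config$seed, 8)

  cohort <- stage("simulate", generate_cohort(config$cohort))
  cohort <- stage("adjust", adjust_cohort_gsm(cohort))
  utils::write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  dict <- lapply(names(cohort), function(nm) {
    list(column = nm, class = class(cohort[[nm]])[1])
  })
  jsonlite::write_json(dict, file.path(dir, "cohort_dictionary.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  repro <- stage("measure", dplyr::bind_rows(
    dplyr::mutate(reproducibility_stats(
      generate_repeat_scans(cohort, "plaque", n = config$n_repeat,
                            seed = seeds[1])), outcome = "plaque_gsm"),
    dplyr::mutate(reproducibility_stats(
      generate_repeat_scans(cohort, "im", n = config$n_repeat,
                            seed = seeds[2])), outcome = "im_gsm")
  ))
  utils::write.table(repro, file.path(dir, "reproducibility.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  results <- list(cohort = cohort, reproducibility = repro)
  sel_fits <- list()
  for (oc in c("plaque_gsm", "im_gsm")) {
    panel <- candidate_panel(oc, data = cohort)
    scr <- stage(paste0("screen:", oc),
                 univariate_screen(cohort, oc, panel))
    sel <- stage(paste0("select:", oc), cross_validated_selection(
      cohort, oc, panel$candidate,
      n_iter = config$n_iter, threshold = config$threshold,
      entry_p = config$entry_p, stay_p = config$stay_p,
      seed = seeds[if (oc == "plaque_gsm") 3 else 4]
    ))
    retained <- sel$retained
    fit <- if (length(retained) > 0) {
      stage(paste0("model:", oc), fit_final_model(cohort, oc, retained))
    } else NULL
    utils::write.table(tidy(sel), file.path(dir, paste0("selection_", oc, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(outcome = oc, retained = retained, n_iter = sel$n_iter,
           threshold = sel$threshold, seed = sel$seed,
           iterations = lapply(sel$iterations, identity)),
      file.path(dir, paste0("selection_", oc, ".json")),
      auto_unbox = TRUE, pretty = TRUE
    )
    if (!is.null(fit)) {
      utils::write.table(tidy(fit), file.path(dir, paste0("model_", oc, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (config$figures && !is.null(fit)) {
      save_fig(autoplot(fit), file.path(dir, paste0("partial_r2_", oc, ".png")))
      save_fig(autoplot(sel), file.path(dir, paste0("selection_", oc, ".png")))
    }
    sel_fits[[oc]] <- list(screen = scr, selection = sel, fit = fit)
  }
  results$selection <- sel_fits

  corr <- stage("stratify:correlation", correlate_gsm(cohort))
  preds_p <- sel_fits$plaque_gsm$selection$retained
  preds_i <- sel_fits$im_gsm$selection$retained
  auc <- if (length(preds_p) && length(preds_i)) {
    stage("stratify:auc", predict_dichotomized_gsm(
      cohort, preds_p, preds_i, seed = seeds[5]))
  } else NULL
  orq <- stage("stratify:or", dplyr::bind_rows(
    or_per_quartile(cohort, "plaque"), or_per_quartile(cohort, "im")
  ))
  grid <- stage("stratify:grid", or_grid(cohort))
  utils::write.table(tidy(grid), file.path(dir, "or_grid.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(auc)) {
    jsonlite::write_json(as.list(glance(auc)), file.path(dir, "auc_comparison.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  if (config$figures) save_fig(autoplot(grid), file.path(dir, "or_grid.png"))
  results <- c(results, list(correlation = corr, auc = auc,
                             or_quartile = orq, or_grid = grid))

  report <- c(
    "# Echolucency analysis run", "",
    sprintf("- subjects: %d (%d plaque-eligible)", nrow(cohort),
            sum(cohort$plaque_present)),
    sprintf("- master seed: %d; cohort seed: %d", config$seed,
            config$cohort$seed), "",
    "## Reproducibility (scan-rescan)", "", md_table(repro), "",
    "## Determinants of plaque-GSM", "",
    if (!is.null(sel_fits$plaque_gsm$fit)) {
      c(md_table(tidy(sel_fits$plaque_gsm$fit)), "",
        sprintf("Whole-model R²: %.1f%%",
                100 * sel_fits$plaque_gsm$fit$r_squared))
    } else "(no predictor retained)", "",
    "## Determinants of IM-GSM", "",
    if (!is.null(sel_fits$im_gsm$fit)) {
      c(md_table(tidy(sel_fits$im_gsm$fit)), "",
        sprintf("Whole-model R²: %.1f%%", 100 * sel_fits$im_gsm$fit$r_squared))
    } else "(no predictor retained)", "",
    "## Plaque-GSM / IM-GSM relationship", "", md_table(corr), "",
    if (!is.null(auc)) c("## AUC comparison (median-dichotomized GSM)", "",
                         md_table(tidy(auc)), "") else NULL,
    "## OR per GSM quartile increase (adjusted)", "", md_table(orq), "",
    "## OR grid (plaque-GSM x IM-GSM quartiles)", "",
    md_table(tidy(grid)[c("plaque_q", "im_q", "n", "or",
                          "conf_low", "conf_high")]), ""
  )
  writeLines(report, file.path(dir, "report.md"))

  manifest <- list(
    package = "echowall",
    version = as.character(utils::packageVersion("echowall")),
    r_version = R.version.string,
    master_seed = config$seed,
    cohort_seed = config$cohort$seed,
    stage_seeds = as.list(setNames(seeds[1:5],
      c("rescan_plaque", "rescan_im", "select_plaque", "select_im", "auc_boot"))),
    n_iter = config$n_iter, threshold = config$threshold
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("report", "written")
  results$dir <- dir
  invisible(results)
}
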