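# End-to-end orchestration: generate -> measure -> stats -> tree.

#' Assemble a run configuration
#'
#' @param design A [study_design()].
#' @param presets Class presets, default [default_presets()].
#' @param render A [render_config()].
#' @param nucleus A [nucleus_config()].
#' @param limits A [qc_limits()].
#' @param params A [spot_params()].
#' @param write_images Write per-cell TIFFs? Truth tables, measurements and
#'   reports are always written.
#' @param truth_only Skip rendering and measurement and run the statistics
#'   on the generator's true per-cell values (fast mode for statistical
#'   experiments).
#' @param outdir Output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(design = default_design(), presets = default_presets(),
                       render = render_config(), nucleus = nucleus_config(),
                       limits = qc_limits(), params = spot_params(),
                       write_images = FALSE, truth_only = FALSE,
                       outdir = tempfile("spermfish_run_")) {
  structure(list(design = design, presets = presets, render = render,
                 nucleus = nucleus, limits = limits, params = params,
                 write_images = write_images, truth_only = truth_only,
                 outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys (all optional): `seed`, `cells_per_subject`, `subjects`
#' (list of `{subject_id, class}`), `truth_only`, `write_images`, `outdir`.
#' Unspecified settings fall back to the package defaults.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  subjects <- if (!is.null(y$subjects))
    do.call(rbind, lapply(y$subjects, as.data.frame))
  else default_design()$subjects
  design <- study_design(subjects,
                         cells_per_subject = y$cells_per_subject %||% 50L,
                         seed = y$seed %||% 1L)
  run_config(design = design,
             write_images = isTRUE(y$write_images),
             truth_only = isTRUE(y$truth_only),
             outdir = y$outdir %||% tempfile("spermfish_run_"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_line <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full pipeline
#'
#' Generates the synthetic dataset, measures every cell (unless
#' `truth_only`), compares ITD and CTA between classes, fits the Gini tree,
#' and writes `truth.csv`, `measurements.csv`, `stats.csv`, `stats.json`,
#' `tree.json`, `subjects.csv`, `report.md` and `run.log` to
#' `config$outdir`. Every artifact is reproducible from the configuration
#' and seed.
#'
#' @param config A [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @return Invisibly, a list with `measurements`, `comparisons`, `tree`,
#'   `dataset`, `outdir`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stopifnot(inherits(config$design, "study_design"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)

  log_line(logf, "generating dataset: %d subjects x %d cells, seed %d",
           nrow(config$design$subjects), config$design$cells_per_subject,
           config$design$seed)
  ds <- generate_dataset(config$design, presets = config$presets,
                         render = !config$truth_only, config = config$render,
                         nucleus = config$nucleus,
                         outdir = if (config$write_images) outdir else NULL)
  if (!config$write_images)
    utils::write.csv(ds$truth, file.path(outdir, "truth.csv"),
                     row.names = FALSE)

  if (config$truth_only) {
    log_line(logf, "truth-only mode: using generator ground truth as measurements")
    meas <- data.frame(cell_id = ds$truth$cell_id,
                       subject_id = ds$truth$subject_id,
                       class = ds$truth$class,
                       itd = ds$truth$true_itd, cta = ds$truth$true_cta,
                       qc_pass = TRUE, qc_reason = "",
                       stringsAsFactors = FALSE)
  } else {
    log_line(logf, "measuring %d cells", nrow(ds$truth))
    meas <- measure_cells(ds, limits = config$limits, params = config$params)
    log_line(logf, "QC pass: %d / %d", sum(meas$qc_pass), nrow(meas))
  }
  utils::write.csv(meas, file.path(outdir, "measurements.csv"),
                   row.names = FALSE)

  comparisons <- lapply(c("itd", "cta"), function(m) {
    cmp <- compare_groups(meas, m)
    log_line(logf, "%s: median low %.3f vs high %.3f, U = %.1f, p = %.3g",
             toupper(m), cmp$median_low, cmp$median_high, cmp$u_statistic,
             cmp$p_two_sided)
    cmp
  })
  names(comparisons) <- c("itd", "cta")
  stats_df <- do.call(rbind, lapply(comparisons, function(cmp)
    data.frame(metric = cmp$metric, n_low = cmp$n_low, n_high = cmp$n_high,
               u_statistic = cmp$u_statistic, z_value = cmp$z_value,
               p_two_sided = cmp$p_two_sided,
               median_low = cmp$median_low, median_high = cmp$median_high,
               q025_low = cmp$interval_low[1L], q975_low = cmp$interval_low[2L],
               q025_high = cmp$interval_high[1L],
               q975_high = cmp$interval_high[2L])))
  utils::write.csv(stats_df, file.path(outdir, "stats.csv"),
                   row.names = FALSE)
  jsonlite::write_json(stats_df, file.path(outdir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(subject_summary(meas), file.path(outdir, "subjects.csv"),
                   row.names = FALSE)

  tree <- gini_tree(meas)
  tree_to_json(tree, file.path(outdir, "tree.json"))
  if (!is.null(tree$root$children))
    log_line(logf, "tree root: %s <= %.4g", tree$root$feature,
             tree$root$threshold)

  write_report(file.path(outdir, "report.md"), config, meas, comparisons,
               tree)
  log_line(logf, "done; outputs in %s", outdir)
  invisible(list(measurements = meas, comparisons = comparisons, tree = tree,
                 dataset = ds, outdir = outdir))
}

write_report <- function(path, config, meas, comparisons, tree) {
  fmt_cmp <- function(cmp) {
    c(sprintf("### %s", toupper(cmp$metric)),
      "",
      sprintf("- low score:  n = %d, median %.3f, 2.5-97.5%% range [%.3f, %.3f]",
              cmp$n_low, cmp$median_low, cmp$interval_low[1L],
              cmp$interval_low[2L]),
      sprintf("- high score: n = %d, median %.3f, 2.5-97.5%% range [%.3f, %.3f]",
              cmp$n_high, cmp$median_high, cmp$interval_high[1L],
              cmp$interval_high[2L]),
      sprintf("- Mann-Whitney U = %.1f (z = %.2f), two-sided p = %.3g",
              cmp$u_statistic, cmp$z_value, cmp$p_two_sided),
      "")
  }
  lines <- c("# Sperm nuclear-architecture run report", "",
             sprintf("- subjects: %s",
                     paste(sprintf("%s (%s)", config$design$subjects$subject_id,
                                   config$design$subjects$class),
                           collapse = ", ")),
             sprintf("- cells per subject: %d", config$design$cells_per_subject),
             sprintf("- seed: %d", config$design$seed),
             sprintf("- mode: %s",
                     if (config$truth_only) "truth only" else "rendered + measured"),
             sprintf("- QC-passing cells: %d / %d", sum(meas$qc_pass),
                     nrow(meas)),
             "", "## Group comparisons", "",
             unlist(lapply(comparisons, fmt_cmp)),
             "## Decision tree", "", "```",
             utils::capture.output(print(tree)), "```", "")
  writeLines(lines, path)
  invisible(path)
}
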