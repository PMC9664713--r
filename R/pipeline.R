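#' Detectable viral load under a configurable threshold
#'
#' Dichotomizes quantitative viral load at an assay/analysis threshold.
#' Detectable is defined inclusively: a load *at or above* the threshold
#' (any quantifiable load at the assay limit counts). The default 20
#' copies/mL is a modern assay quantification limit; 1000 copies/mL is the
#' programmatic treatment-failure threshold used by several national
#' guidelines.
#'
#' @param viral_load Viral load(s) in copies/mL.
#' @param threshold Detection threshold in copies/mL (default 20).
#' @return Logical vector.
#' @examples
#' vl_detectable_at(c(0, 19, 20, 1500), threshold = 20)
#' @export
vl_detectable_at <- function(viral_load, threshold = 20) {
  if (any(!is.na(viral_load) & viral_load < 0))
    stop("`viral_load` must be non-negative", call. = FALSE)
  viral_load >= threshold
}

#' Pipeline configuration
#'
#' Bundles everything one reproducible run needs: file locations, the
#' outcome threshold, the cut-off grid, the measures to evaluate and
#' (when simulating) the full simulation block.
#'
#' @param cohort_path Where the cohort CSV is written/read.
#' @param results_dir Directory for result tables and the report.
#' @param outcome_threshold Viral-load threshold in copies/mL (metadata
#'   recorded in outputs; the simulator draws outcome status directly).
#' @param cutoffs Adherence cut-off grid (see [cutoff_grid()]).
#' @param measures Measure labels to evaluate (see [default_measures()]).
#' @param simulation A [sim_config()] or a named list of its fields.
#' @param verbose Log per-stage progress to stderr?
#' @return An object of class `pipeline_config`.
#' @seealso [read_pipeline_config()], [run_simulate()], [run_evaluate()],
#'   [run_regress()], [run_report()]
#' @export
pipeline_config <- function(cohort_path = "cohort.csv",
                            results_dir = "results",
                            outcome_threshold = 20,
                            cutoffs = c(80, 85, 90, 95, 100),
                            measures = default_measures(),
                            simulation = sim_config(),
                            verbose = TRUE) {
  if (!is.numeric(outcome_threshold) || outcome_threshold < 0)
    stop("invalid pipeline_config field `outcome_threshold`: must be non-negative",
         call. = FALSE)
  cutoffs <- cutoff_grid(cutoffs)
  if (is.list(simulation) && !inherits(simulation, "sim_config")) {
    if (!is.null(simulation$regimen_class_probs))
      simulation$regimen_class_probs <- unlist(simulation$regimen_class_probs)
    simulation <- do.call(sim_config, simulation)
  }
  structure(list(cohort_path = cohort_path, results_dir = results_dir,
                 outcome_threshold = outcome_threshold, cutoffs = cutoffs,
                 measures = measures, simulation = simulation,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML/JSON
#'
#' Any subset of [pipeline_config()] fields may be present; the
#' `simulation` block accepts any subset of [sim_config()] fields.
#'
#' @param path File path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

stage_log <- function(config, fmt, ...) {
  if (config$verbose)
    message(sprintf("[adheval %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
}

#' Pipeline stage: simulate a cohort and write it to disk
#'
#' @param config A `pipeline_config`.
#' @return The cohort CSV path, invisibly.
#' @export
run_simulate <- function(config) {
  t0 <- Sys.time()
  cohort <- simulate_cohort(config$simulation)
  dir.create(dirname(config$cohort_path), showWarnings = FALSE, recursive = TRUE)
  write_cohort(cohort, config$cohort_path)
  stage_log(config, "simulate: %d participants -> %s (%.2fs)",
            nrow(cohort), config$cohort_path,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(config$cohort_path)
}

# measures whose components are all available in the panel; RTMM-containing
# measures drop out (with a warning) when no participant has device data
available_measures <- function(panel, measures) {
  ok <- vapply(measures, function(m) {
    cols <- measure_components(m)
    all(cols %in% names(panel)) &&
      any(stats::complete.cases(panel[cols]))
  }, TRUE)
  if (any(!ok))
    warning("skipping measure(s) with no data: ",
            paste(measures[!ok], collapse = ", "), call. = FALSE)
  measures[ok]
}

#' Pipeline stage: score, classify and evaluate diagnostic accuracy
#'
#' Reads the cohort, builds the adherence panel, and writes the panel, the
#' diagnostic accuracy table across the cut-off grid, the ROC vertex
#' table, and an ROC summary (AUC and closest-to-top-left optimal cut-off
#' per measure). Measures with no data (e.g. RTMM in an unmonitored
#' cohort) are skipped with a warning.
#'
#' @param config A `pipeline_config`.
#' @return Named list of output file paths, invisibly.
#' @export
run_evaluate <- function(config) {
  t0 <- Sys.time()
  cohort <- read_cohort(config$cohort_path)
  panel <- build_panel(cohort)
  measures <- available_measures(panel, config$measures)
  dir.create(config$results_dir, showWarnings = FALSE, recursive = TRUE)

  paths <- list(
    panel = file.path(config$results_dir, "adherence_panel.csv"),
    diagnostics = file.path(config$results_dir, "diagnostic_table.csv"),
    roc_points = file.path(config$results_dir, "roc_points.csv"),
    roc_summary = file.path(config$results_dir, "roc_summary.csv")
  )
  write_panel(panel, paths$panel)

  dt <- diagnostic_table(panel, measures = measures, grid = config$cutoffs)
  dt$outcome_threshold <- config$outcome_threshold
  readr::write_csv(dt, paths$diagnostics, na = "")

  curves <- roc_curves(panel, measures = measures)
  pts <- dplyr::bind_rows(lapply(names(curves), function(nm)
    dplyr::mutate(curves[[nm]]$points, measure = nm, .before = 1)))
  readr::write_csv(pts, paths$roc_points, na = "")

  summary <- dplyr::bind_rows(lapply(names(curves), function(nm) {
    oc <- optimal_cutoff(curves[[nm]])
    tibble::tibble(measure = nm, auc = curves[[nm]]$auc,
                   n_cases = curves[[nm]]$n_cases,
                   n_controls = curves[[nm]]$n_controls,
                   optimal_cutoff = as.numeric(oc),
                   optimal_sensitivity = attr(oc, "sensitivity") %||% NA_real_,
                   optimal_specificity = attr(oc, "specificity") %||% NA_real_)
  }))
  readr::write_csv(summary, paths$roc_summary, na = "")

  stage_log(config, "evaluate: %d measures x %d cutoffs -> %s (%.2fs)",
            length(measures), length(config$cutoffs), config$results_dir,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(paths)
}

#' Pipeline stage: adjusted logistic regressions
#'
#' Runs [regression_sweep()] over the configured measures and cut-offs and
#' writes the long fit table (one row per measure, cut-off and term,
#' including separation flags); failed cells go to a companion CSV.
#'
#' @param config A `pipeline_config`.
#' @return The fit table path, invisibly.
#' @export
run_regress <- function(config) {
  t0 <- Sys.time()
  panel <- build_panel(read_cohort(config$cohort_path))
  measures <- available_measures(panel, config$measures)
  dir.create(config$results_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- withCallingHandlers(
    regression_sweep(panel, measures = measures, grid = config$cutoffs),
    warning = function(w) {
      stage_log(config, "regress: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  path <- file.path(config$results_dir, "regression_fits.csv")
  readr::write_csv(fits, path, na = "")
  failures <- attr(fits, "failures")
  if (!is.null(failures) && nrow(failures) > 0)
    readr::write_csv(failures,
                     file.path(config$results_dir, "regression_failures.csv"))
  stage_log(config, "regress: %d fitted cells -> %s (%.2fs)",
            nrow(dplyr::distinct(fits, .data$measure, .data$cutoff)), path,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(path)
}

#' Pipeline stage: human-readable summary report
#'
#' Writes a plain-text report: cohort disposition, outcome prevalence,
#' per-measure AUC and optimal cut-off, and the regression cells
#' significant at the 0.05 level.
#'
#' @param config A `pipeline_config`.
#' @return The report path, invisibly.
#' @export
run_report <- function(config) {
  panel <- build_panel(read_cohort(config$cohort_path))
  measures <- suppressWarnings(available_measures(panel, config$measures))
  curves <- roc_curves(panel, measures = measures)
  fits <- suppressWarnings(
    regression_sweep(panel, measures = measures, grid = config$cutoffs))

  lines <- c(
    "Adherence measurement evaluation report",
    "=======================================",
    sprintf("Participants analysed: %d", nrow(panel)),
    sprintf("Detectable viral load (>= %g copies/mL): %d (%.1f%%)",
            config$outcome_threshold, sum(panel$vl_detectable),
            100 * mean(panel$vl_detectable)),
    "",
    "Discrimination by measure (empirical ROC):",
    sprintf("  %-12s AUC %.3f  optimal cut-off %s", names(curves),
            vapply(curves, function(cv) cv$auc, 0),
            vapply(curves, function(cv) {
              oc <- optimal_cutoff(cv)
              if (is.na(oc)) "undefined"
              else sprintf("%.1f%% (sens %.0f%%, spec %.0f%%)", oc,
                           attr(oc, "sensitivity"), attr(oc, "specificity"))
            }, "")),
    "",
    "Adjusted regression cells with p < 0.05 for nonadherence:"
  )
  sig <- dplyr::filter(fits, .data$term == "nonadherent", .data$p_value < 0.05)
  if (nrow(sig) == 0) {
    lines <- c(lines, "  (none)")
  } else {
    lines <- c(lines, sprintf(
      "  %-12s cut-off %3g%%: OR %.2f (95%% CI %.2f-%.2f), p = %.4f%s",
      sig$measure, sig$cutoff, sig$odds_ratio, sig$conf_low, sig$conf_high,
      sig$p_value, ifelse(sig$separation, " [separation]", "")))
  }
  dir.create(config$results_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$results_dir, "report.txt")
  writeLines(lines, path)
  stage_log(config, "report -> %s", path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Simulate (when configured), evaluate, regress, report.
#'
#' @param config A `pipeline_config`.
#' @param simulate Generate the cohort first? (Set `FALSE` to evaluate an
#'   existing cohort CSV.)
#' @return Named list of output paths, invisibly.
#' @export
run_pipeline <- function(config, simulate = TRUE) {
  if (simulate) run_simulate(config)
  eval_paths <- run_evaluate(config)
  regress_path <- run_regress(config)
  report_path <- run_report(config)
  invisible(c(eval_paths, list(regression = regress_path, report = report_path)))
}
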