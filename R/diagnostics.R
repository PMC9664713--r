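#' Cross-tabulate adherence flags against virological outcome
#'
#' Builds the 2x2 confusion counts with the orientation used throughout
#' the package: the positive *condition* is a detectable viral load and the
#' positive *test* is a nonadherent classification. So `tp` counts
#' nonadherent participants with detectable viral load, `tn` adherent
#' participants with suppressed viral load.
#'
#' @param flags Character vector of `"adherent"` / `"nonadherent"`.
#' @param outcomes Logical vector: detectable viral load?
#' @return A named list of class `confusion_counts` with `tp`, `fp`, `fn`,
#'   `tn` and `n`.
#' @examples
#' confusion(c("nonadherent", "adherent"), c(TRUE, FALSE))
#' @export
confusion <- function(flags, outcomes) {
  if (length(flags) != length(outcomes))
    stop("`flags` and `outcomes` must have equal length", call. = FALSE)
  if (anyNA(flags) || anyNA(outcomes))
    stop("`flags` and `outcomes` must not contain missing values", call. = FALSE)
  if (!all(flags %in% c("adherent", "nonadherent")))
    stop("flags must be \"adherent\" or \"nonadherent\"", call. = FALSE)
  if (!is.logical(outcomes))
    stop("`outcomes` must be logical", call. = FALSE)
  pos <- flags == "nonadherent"
  out <- list(tp = sum(pos & outcomes), fp = sum(pos & !outcomes),
              fn = sum(!pos & outcomes), tn = sum(!pos & !outcomes),
              n = length(flags))
  class(out) <- "confusion_counts"
  out
}

#' Accuracy metrics from confusion counts
#'
#' Sensitivity, specificity, positive and negative predictive value on the
#' percent scale. A zero denominator yields `NA` (an explicit undefined
#' marker), never a number: e.g. PPV is undefined at a cut-off that flags
#' nobody as nonadherent.
#'
#' @param counts A `confusion_counts` object from [confusion()].
#' @return A named list: `sensitivity`, `specificity`, `ppv`, `npv`
#'   (percents or `NA`).
#' @examples
#' diagnostic_metrics(confusion(c("nonadherent", "adherent"), c(TRUE, TRUE)))
#' @export
diagnostic_metrics <- function(counts) {
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(
    sensitivity = ratio(counts$tp, counts$tp + counts$fn),
    specificity = ratio(counts$tn, counts$tn + counts$fp),
    ppv = ratio(counts$tp, counts$tp + counts$fp),
    npv = ratio(counts$tn, counts$tn + counts$fn)
  )
}

measure_components <- function(measure) {
  switch(measure,
    "sr" = "sr_adherence",
    "pr" = "pr_adherence",
    "rtmm" = "rtmm_adherence",
    "sr+pr" = c("sr_adherence", "pr_adherence"),
    "sr+pr+rtmm" = c("sr_adherence", "pr_adherence", "rtmm_adherence"),
    stop(sprintf("unknown measure \"%s\"", measure), call. = FALSE)
  )
}

#' Default measure set
#'
#' The five comparisons of interest: each channel alone, self-report
#' combined with pharmacy refill, and all three channels combined.
#' @return Character vector of measure labels.
#' @export
default_measures <- function() c("sr", "pr", "rtmm", "sr+pr", "sr+pr+rtmm")

#' Continuous score for a (possibly composite) measure
#'
#' Single measures return their panel column; composites return the
#' per-participant minimum of their components ([composite_score()]).
#' Participants missing any component (e.g. no RTMM device) get `NA`, so
#' RTMM-containing measures are automatically restricted to the monitored
#' arm.
#'
#' @param panel A panel tibble from [build_panel()].
#' @param measure One of `"sr"`, `"pr"`, `"rtmm"`, `"sr+pr"`,
#'   `"sr+pr+rtmm"`.
#' @return Numeric vector of adherence percents (with `NA`s).
#' @export
measure_scores <- function(panel, measure) {
  cols <- measure_components(measure)
  missing_cols <- setdiff(cols, names(panel))
  if (length(missing_cols) > 0)
    stop("panel lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  do.call(composite_score, unname(as.list(panel[cols])))
}

#' Diagnostic accuracy table across measures and cut-offs
#'
#' For every (measure, cut-off) cell: dichotomize the measure's continuous
#' score at the cut-off, cross-tabulate against detectable viral load, and
#' report confusion counts with sensitivity, specificity, PPV and NPV.
#' Participants missing the measure (no RTMM device, unknown outcome) are
#' excluded from that measure's rows; `n` records the evaluated count.
#'
#' @param panel A panel tibble from [build_panel()].
#' @param measures Measure labels (see [default_measures()]).
#' @param grid A [cutoff_grid()].
#' @return A tibble: `measure`, `cutoff`, `n`, `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `specificity`, `ppv`, `npv` (percents, `NA` =
#'   undefined).
#' @examples
#' panel <- build_panel(simulate_cohort(sim_config(n_participants = 60)))
#' diagnostic_table(panel, measures = c("sr", "pr"))
#' @export
diagnostic_table <- function(panel, measures = default_measures(),
                             grid = cutoff_grid()) {
  if (nrow(panel) == 0) stop("panel is empty", call. = FALSE)
  grid <- cutoff_grid(grid)
  rows <- lapply(measures, function(m) {
    scores <- measure_scores(panel, m)
    keep <- !is.na(scores) & !is.na(panel$vl_detectable)
    if (!any(keep))
      stop(sprintf("measure \"%s\" is absent for all participants", m),
           call. = FALSE)
    s <- scores[keep]
    y <- panel$vl_detectable[keep]
    dplyr::bind_rows(lapply(grid, function(cutoff) {
      cc <- confusion(dichotomize(s, cutoff), y)
      met <- diagnostic_metrics(cc)
      tibble::tibble(measure = m, cutoff = cutoff, n = cc$n,
                     tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
                     sensitivity = met$sensitivity,
                     specificity = met$specificity,
                     ppv = met$ppv, npv = met$npv)
    }))
  })
  dplyr::bind_rows(rows)
}

#' Empirical ROC curve of an adherence measure
#'
#' Risk orientation: *low* adherence predicts a detectable viral load, so
#' the test is "score at or below threshold". The curve sweeps every
#' distinct observed score as a threshold plus a `-Inf` origin, giving a
#' vertex sequence from (0, 0) to (1, 1); tied scores collapse into a
#' single vertex. The AUC is the trapezoidal area under the vertices,
#' which equals the Mann-Whitney probability that a random case scores
#' below a random control, counting ties as one half.
#'
#' @param scores Adherence percents (no missing values).
#' @param outcomes Logical: detectable viral load? Both classes must be
#'   present.
#' @return An object of class `roc_curve`: a list with `points` (tibble of
#'   `threshold`, `fpr`, `tpr`), `auc`, `n_cases`, `n_controls`.
#' @examples
#' roc_curve(c(97, 85, 99, 90), c(TRUE, TRUE, FALSE, FALSE))
#' @export
roc_curve <- function(scores, outcomes) {
  if (length(scores) != length(outcomes))
    stop("`scores` and `outcomes` must have equal length", call. = FALSE)
  if (anyNA(scores) || anyNA(outcomes))
    stop("`scores` and `outcomes` must not contain missing values", call. = FALSE)
  if (!any(outcomes))
    stop("no positive outcomes (detectable viral load) present", call. = FALSE)
  if (all(outcomes))
    stop("no negative outcomes (suppressed viral load) present", call. = FALSE)

  thr <- c(-Inf, sort(unique(scores)))
  n_cases <- sum(outcomes)
  n_controls <- sum(!outcomes)
  tpr <- vapply(thr, function(t) sum(scores[outcomes] <= t) / n_cases, 0)
  fpr <- vapply(thr, function(t) sum(scores[!outcomes] <= t) / n_controls, 0)
  pts <- tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr)
  auc_val <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc_val,
                 n_cases = n_cases, n_controls = n_controls),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d vertices, %d cases / %d controls, AUC = %.3f\n",
              nrow(x$points), x$n_cases, x$n_controls, x$auc))
  invisible(x)
}

#' Area under the empirical ROC curve
#'
#' Trapezoidal area of [roc_curve()]; 0.5 means no discriminatory
#' capacity, 1 perfect discrimination (for screening, 0.7 or higher is
#' usually considered sufficient).
#'
#' @inheritParams roc_curve
#' @return AUC as a fraction in \[0, 1\].
#' @export
auc <- function(scores, outcomes) roc_curve(scores, outcomes)$auc

#' Optimal adherence cut-off: closest to the top-left ROC corner
#'
#' The adherence threshold of the interior ROC vertex minimizing the
#' Euclidean distance to the perfect-classification corner (fpr = 0,
#' tpr = 1). Ties are broken toward the higher-sensitivity vertex, then the
#' lower threshold. The curve's endpoints (classify nobody / everybody) are
#' not candidate cut-offs; a degenerate two-point curve has no interior
#' vertex and yields `NA`.
#'
#' @param curve A `roc_curve` object.
#' @return The optimal threshold (adherence percent), with the vertex's
#'   `sensitivity`, `specificity` and `distance` attached as attributes;
#'   `NA` when undefined.
#' @export
optimal_cutoff <- function(curve) {
  if (!inherits(curve, "roc_curve"))
    stop("`curve` must be a roc_curve object", call. = FALSE)
  pts <- curve$points
  if (nrow(pts) <= 2) {
    out <- NA_real_
    attr(out, "distance") <- NA_real_
    return(out)
  }
  interior <- pts[-c(1, nrow(pts)), ]
  dist <- sqrt(interior$fpr^2 + (1 - interior$tpr)^2)
  ord <- order(dist, -interior$tpr, interior$threshold)
  best <- ord[1]
  out <- interior$threshold[best]
  attr(out, "sensitivity") <- 100 * interior$tpr[best]
  attr(out, "specificity") <- 100 * (1 - interior$fpr[best])
  attr(out, "distance") <- dist[best]
  out
}

#' ROC curves for a set of adherence measures
#'
#' Convenience wrapper: one [roc_curve()] per measure on its complete
#' cases.
#'
#' @param panel A panel tibble from [build_panel()].
#' @param measures Measure labels (see [default_measures()]).
#' @return Named list of `roc_curve` objects.
#' @export
roc_curves <- function(panel, measures = default_measures()) {
  out <- lapply(measures, function(m) {
    scores <- measure_scores(panel, m)
    keep <- !is.na(scores) & !is.na(panel$vl_detectable)
    roc_curve(scores[keep], panel$vl_detectable[keep])
  })
  names(out) <- measures
  out
}

#' Plot one or more ROC curves
#'
#' Sensitivity against 1 - specificity with the chance diagonal; the
#' closest-to-top-left optimal cut-off of each curve is marked with a
#' point.
#'
#' @param curves A `roc_curve` or a named list of them (see
#'   [roc_curves()]).
#' @return A ggplot object.
#' @export
plot_roc <- function(curves) {
  if (inherits(curves, "roc_curve")) curves <- list(measure = curves)
  df <- dplyr::bind_rows(lapply(names(curves), function(nm) {
    dplyr::mutate(curves[[nm]]$points,
                  measure = sprintf("%s (AUC %.2f)", nm, curves[[nm]]$auc))
  }))
  opt <- dplyr::bind_rows(lapply(names(curves), function(nm) {
    oc <- optimal_cutoff(curves[[nm]])
    if (is.na(oc)) return(NULL)
    tibble::tibble(measure = sprintf("%s (AUC %.2f)", nm, curves[[nm]]$auc),
                   fpr = 1 - attr(oc, "specificity") / 100,
                   tpr = attr(oc, "sensitivity") / 100)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                        colour = .data$measure)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (nrow(opt) > 0)
    p <- p + ggplot2::geom_point(data = opt, size = 2)
  p
}

#' Trial disposition percentages
#'
#' Recomputes the flow percentages of a trial report from its disposition
#' counts: the completion rate among enrolled participants and the
#' suppressed / detectable split among completers.
#'
#' @param enrolled Participants enrolled and randomized.
#' @param completed Participants completing follow-up with an outcome.
#' @param suppressed Completers with a suppressed (undetectable) viral
#'   load.
#' @return A tibble with the three counts and `completed_pct`,
#'   `suppressed_pct`, `detectable_pct`.
#' @examples
#' disposition_summary(249, 233, 161)
#' @export
disposition_summary <- function(enrolled, completed, suppressed) {
  if (completed > enrolled || suppressed > completed)
    stop("disposition counts must be nested: suppressed <= completed <= enrolled",
         call. = FALSE)
  tibble::tibble(
    enrolled = enrolled, completed = completed, suppressed = suppressed,
    completed_pct = 100 * completed / enrolled,
    suppressed_pct = 100 * suppressed / completed,
    detectable_pct = 100 * (completed - suppressed) / completed
  )
}
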