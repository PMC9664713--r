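#' The adherence cut-off grid
#'
#' A strictly increasing vector of percent cut-offs at which continuous
#' adherence is dichotomized. The default grid spans the range within which
#' viral suppression is plausibly attainable: 80% (modern, forgiving
#' regimens) up to perfect adherence.
#'
#' @param cutoffs Percent cut-offs, each in (0, 100], strictly increasing.
#' @return The validated numeric grid.
#' @examples
#' cutoff_grid()          # 80 85 90 95 100
#' cutoff_grid(c(75, 90))
#' @export
cutoff_grid <- function(cutoffs = c(80, 85, 90, 95, 100)) {
  if (!is.numeric(cutoffs) || length(cutoffs) == 0 || anyNA(cutoffs))
    stop("`cutoffs` must be a non-empty numeric vector", call. = FALSE)
  if (any(cutoffs <= 0) || any(cutoffs > 100))
    stop("each cutoff must be in (0, 100]", call. = FALSE)
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("`cutoffs` must be strictly increasing", call. = FALSE)
  cutoffs
}

#' Dichotomize continuous adherence at a cut-off
#'
#' A participant is classified *nonadherent* when adherence is strictly
#' below the cut-off; equality counts as adherent, so a 100% cut-off flags
#' only imperfect adherence.
#'
#' @param adherence Adherence percent(s) in \[0, 100\]; `NA` passes through.
#' @param cutoff A single cut-off percent in \[0, 100\].
#' @return Character vector of `"adherent"` / `"nonadherent"` (or `NA`).
#' @examples
#' dichotomize(c(90, 95, 100), 95) # nonadherent, adherent, adherent
#' @export
dichotomize <- function(adherence, cutoff) {
  if (length(cutoff) != 1 || is.na(cutoff) || cutoff < 0 || cutoff > 100)
    stop("`cutoff` must be a single percent in [0, 100]", call. = FALSE)
  if (any(!is.na(adherence) & (adherence < 0 | adherence > 100)))
    stop("`adherence` must be in [0, 100]", call. = FALSE)
  ifelse(adherence < cutoff, "nonadherent", "adherent")
}

#' Combine adherence flags by the any-measure rule
#'
#' A participant is nonadherent on the composite if they are nonadherent on
#' *any* of the combined measures. Input flags are combined elementwise
#' when given as a list of vectors.
#'
#' @param ... One or more flag vectors (`"adherent"`/`"nonadherent"`),
#'   recycled to a common length.
#' @return The combined flag vector.
#' @examples
#' combine_flags(c("adherent", "adherent"), c("nonadherent", "adherent"))
#' @export
combine_flags <- function(...) {
  flags <- list(...)
  if (length(flags) == 0)
    stop("at least one flag vector is required", call. = FALSE)
  bad <- unlist(lapply(flags, function(f) f[!is.na(f)]))
  if (!all(bad %in% c("adherent", "nonadherent")))
    stop("flags must be \"adherent\" or \"nonadherent\"", call. = FALSE)
  any_non <- Reduce(`|`, lapply(flags, function(f) f == "nonadherent"))
  ifelse(any_non, "nonadherent", "adherent")
}

#' Continuous composite adherence score
#'
#' The per-participant minimum over the component scores. The minimum is
#' the unique scalar whose thresholding reproduces the any-measure rule at
#' every cut-off simultaneously:
#' `dichotomize(composite_score(s), c)` equals
#' `combine_flags(dichotomize(s1, c), dichotomize(s2, c), ...)` for all `c`.
#'
#' @param ... One or more adherence percent vectors, recycled to a common
#'   length. `NA` components propagate (a composite involving a missing
#'   channel is missing).
#' @return The elementwise minimum.
#' @examples
#' composite_score(c(96, 100), c(92, 98), c(99, 95)) # 92 95
#' @export
composite_score <- function(...) {
  scores <- list(...)
  if (length(scores) == 0)
    stop("at least one score vector is required", call. = FALSE)
  for (s in scores)
    if (any(!is.na(s) & (s < 0 | s > 100)))
      stop("adherence scores must be in [0, 100]", call. = FALSE)
  do.call(pmin, c(scores, list(na.rm = FALSE)))
}

#' Long-format classification table over measures and cut-offs
#'
#' Dichotomizes every requested measure column of an adherence panel at
#' every cut-off of the grid.
#'
#' @param panel A panel tibble from [build_panel()].
#' @param measures Panel column names to classify (default the three
#'   channels).
#' @param grid A [cutoff_grid()].
#' @return A long tibble: `participant_id`, `measure`, `cutoff`, `flag`.
#' @export
classification_table <- function(panel,
                                 measures = c("sr_adherence", "pr_adherence",
                                              "rtmm_adherence"),
                                 grid = cutoff_grid()) {
  grid <- cutoff_grid(grid)
  missing_cols <- setdiff(measures, names(panel))
  if (length(missing_cols) > 0)
    stop("panel lacks measure column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  rows <- lapply(measures, function(m) {
    lapply(grid, function(co) {
      tibble::tibble(participant_id = panel$participant_id,
                     measure = m, cutoff = co,
                     flag = dichotomize(panel[[m]], co))
    })
  })
  dplyr::bind_rows(rows)
}
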