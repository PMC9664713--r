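#' Self-reported adherence percentage
#'
#' Adherence over a recall window from the interview questions "how many
#' pills do you take per day?" and "how many pills did you miss?":
#' \deqn{100 \times \frac{(d \cdot p) - m}{d \cdot p}}
#' with \eqn{d} days in the window, \eqn{p} pills per day and \eqn{m}
#' missed pills. The arithmetic is exact (a rational ratio scaled to
#' percent); the result is capped at 100 for uniformity with the other
#' channels, although with valid inputs it cannot exceed it.
#'
#' @param days_in_window Days covered by the recall window (> 0). The
#'   analysis window is the inter-visit period; use 30 as a fallback when
#'   the window length is unrecorded.
#' @param pills_per_day Prescribed pills per day (> 0).
#' @param missed_pills Reported missed pills, between 0 and
#'   `days_in_window * pills_per_day`.
#' @return Adherence percent in \[0, 100\]. Vectorized over all arguments.
#' @examples
#' self_report_adherence(30, 1, 3) # 90
#' @export
self_report_adherence <- function(days_in_window, pills_per_day, missed_pills) {
  if (any(days_in_window <= 0) || any(pills_per_day <= 0))
    stop("`days_in_window` and `pills_per_day` must be positive", call. = FALSE)
  prescribed <- days_in_window * pills_per_day
  if (any(is.na(missed_pills)) || any(missed_pills < 0) || any(missed_pills > prescribed))
    stop("`missed_pills` must be between 0 and days_in_window * pills_per_day",
         call. = FALSE)
  pmin(100, (prescribed - missed_pills) / prescribed * 100)
}

#' Pharmacy refill adherence percentage
#'
#' Pills presumed taken over the inter-visit interval, from the dispensing
#' ledger:
#' \deqn{100 \times \frac{(\mathrm{dispensed}_{prev} +
#'   \mathrm{returned}_{prev}) - \mathrm{returned}_{cur}}
#'   {\mathrm{days} \cdot \mathrm{pills/day}}}
#' truncated at 100% (supply can legitimately exceed the prescription).
#' When the current returned-pill count is unknown (`NA`), all pills are
#' assumed taken as prescribed and the adherence is 100%.
#'
#' @param dispensed_prev Pills dispensed at the previous visit.
#' @param returned_prev Leftover pills returned at the previous visit.
#' @param returned_current Leftover pills returned (or recalled) at the
#'   current visit; `NA` when unknown.
#' @param days_between_visits Days between the two visits (> 0).
#' @param pills_per_day Prescribed pills per day (> 0).
#' @return Adherence percent in \[0, 100\]. Vectorized over all arguments.
#' @examples
#' pharmacy_refill_adherence(60, 5, 10, 56, 1) # 55/56 * 100
#' pharmacy_refill_adherence(70, 0, 0, 56, 1)  # raw 125%, capped to 100
#' @export
pharmacy_refill_adherence <- function(dispensed_prev, returned_prev,
                                      returned_current, days_between_visits,
                                      pills_per_day) {
  if (any(days_between_visits <= 0) || any(pills_per_day <= 0))
    stop("`days_between_visits` and `pills_per_day` must be positive", call. = FALSE)
  if (any(dispensed_prev < 0) || any(returned_prev < 0) ||
      any(!is.na(returned_current) & returned_current < 0))
    stop("pharmacy pill counts must be non-negative", call. = FALSE)
  taken <- dispensed_prev + returned_prev - returned_current
  if (any(!is.na(taken) & taken < 0))
    stop("more pills returned at the current visit than were available",
         call. = FALSE)
  raw <- taken / (days_between_visits * pills_per_day) * 100
  out <- pmin(100, raw)
  out[is.na(returned_current)] <- 100  # unknown leftover: assume all taken
  out
}

#' RTMM adherence percentage
#'
#' Device-opening adherence from a real-time medication monitoring pill
#' box: openings recorded over the window divided by the number of expected
#' openings under the prescription (days times dosing moments per day),
#' scaled to percent. Openings can exceed expectations (curiosity openings,
#' refills); the value is capped at 100 so downstream cut-off logic sees a
#' \[0, 100\] scale.
#'
#' @param openings Recorded device openings (>= 0).
#' @param days_in_window Days in the monitoring window (> 0).
#' @param dosing_moments_per_day Prescribed dosing moments per day (> 0).
#' @return Adherence percent in \[0, 100\]. Vectorized over all arguments.
#' @examples
#' rtmm_adherence(28, 56, 1) # 50
#' @export
rtmm_adherence <- function(openings, days_in_window, dosing_moments_per_day) {
  expected <- days_in_window * dosing_moments_per_day
  if (any(expected <= 0))
    stop("expected openings (days * dosing moments) must be positive", call. = FALSE)
  if (any(!is.na(openings) & openings < 0))
    stop("`openings` must be non-negative", call. = FALSE)
  pmin(100, openings / expected * 100)
}

#' Build the per-participant adherence panel
#'
#' Applies the three channel formulas row-wise to a cohort and carries the
#' outcome and covariates through. RTMM adherence is `NA` for participants
#' without device data. Row-level domain errors are re-raised with the
#' participant id.
#'
#' @param cohort A validated cohort tibble (see [simulate_cohort()],
#'   [read_cohort()]).
#' @return A tibble with one row per participant: `participant_id`,
#'   `sr_adherence`, `pr_adherence`, `rtmm_adherence` (percent scales),
#'   `vl_detectable`, `sex`, `regimen_class`, and `true_adherence` when the
#'   cohort carries it.
#' @examples
#' panel <- build_panel(simulate_cohort(sim_config(n_participants = 10)))
#' @export
build_panel <- function(cohort) {
  validate_cohort(cohort)
  with_id <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("adherence scoring failed (%s)", conditionMessage(e)),
           call. = FALSE)
    })
  }
  sr <- with_id(self_report_adherence(cohort$days_in_window,
                                      cohort$pills_per_day,
                                      cohort$sr_missed_pills))
  pr <- with_id(pharmacy_refill_adherence(cohort$pr_dispensed_prev,
                                          cohort$pr_returned_prev,
                                          cohort$pr_returned_current,
                                          cohort$days_in_window,
                                          cohort$pills_per_day))
  rtmm <- with_id(rtmm_adherence(cohort$rtmm_openings,
                                 cohort$days_in_window,
                                 cohort$dosing_moments_per_day))
  out <- tibble::tibble(
    participant_id = cohort$participant_id,
    sr_adherence = sr,
    pr_adherence = pr,
    rtmm_adherence = rtmm,
    vl_detectable = cohort$vl_detectable,
    sex = cohort$sex,
    regimen_class = cohort$regimen_class
  )
  if ("true_adherence" %in% names(cohort))
    out$true_adherence <- cohort$true_adherence
  out
}

#' Write an adherence panel as CSV
#'
#' @param panel A panel tibble from [build_panel()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel, path, na = "")
  invisible(path)
}
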