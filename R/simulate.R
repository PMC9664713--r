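#' Simulate a synthetic adherence cohort
#'
#' Generates one participant row per person for the final (week-48) visit
#' window. A latent adherence propensity is drawn from the configured beta
#' mixture; actual intake is a Bernoulli event per prescribed dosing moment
#' at that propensity, and all three measurement channels observe that one
#' underlying event stream:
#'
#' * **Self-report**: the true missed-pill count is shrunk by
#'   `sr_underreport_factor` and rounded; with probability
#'   `sr_zero_report_prob` the participant reports zero missed pills
#'   regardless of the truth.
#' * **Pharmacy refill**: the dispensing ledger covers the window exactly;
#'   with probability `pr_surplus_prob` a leftover surplus returned at the
#'   previous visit adds to the supply. The returned-pill count at the
#'   current visit equals the true leftover, but is unavailable (`NA`) with
#'   probability `pr_unknown_leftover_prob`.
#' * **RTMM**: each actual intake produces an opening record unless lost to
#'   an outage (per-dose probability `rtmm_outage_day_prob`); with
#'   probability `rtmm_pocket_dose_prob` the participant pocket-doses once
#'   in the window, taking 2--4 doses out in a single opening.
#'
#' The week-48 viral-load status is drawn from the logistic outcome model in
#' the config, using the *realized* intake fraction (`true_adherence`).
#'
#' The generator seeds R's RNG from `config$seed`, so an identical config
#' reproduces an identical cohort.
#'
#' @param config A [sim_config()] object.
#' @param rtmm_arm_fraction Fraction of participants carrying the RTMM
#'   device (default 1: all). Device openings are generated for everyone and
#'   blanked (`NA`) outside a randomly chosen RTMM arm, mirroring a trial in
#'   which only one arm is electronically monitored.
#'
#' @return A tibble with one row per participant: `participant_id`, `sex`
#'   (`"female"`/`"male"`), `regimen_class`, `true_adherence` (realized
#'   intake fraction, a simulator-only column absent from real data),
#'   `pills_per_day`, `days_in_window`, `dosing_moments_per_day`,
#'   `sr_missed_pills`, `pr_dispensed_prev`, `pr_returned_prev`,
#'   `pr_returned_current` (`NA` = unknown leftover), `rtmm_openings`
#'   (`NA` = no device), `rtmm_expected_openings`, `vl_detectable`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 20, seed = 42))
#' @export
simulate_cohort <- function(config, rtmm_arm_fraction = 1) {
  config <- validate_sim_config(config)
  if (!is.numeric(rtmm_arm_fraction) || rtmm_arm_fraction < 0 || rtmm_arm_fraction > 1)
    stop("`rtmm_arm_fraction` must be in [0, 1]", call. = FALSE)

  set.seed(config$seed)
  n <- config$n_participants
  days <- config$days_in_window
  ppd <- config$pills_per_day
  moments <- config$dosing_moments_per_day
  pills_per_dose <- ppd %/% moments
  total_doses <- days * moments
  total_pills <- days * ppd

  sex <- ifelse(stats::runif(n) < config$prop_female, "female", "male")
  regimen <- sample(names(config$regimen_class_probs), n, replace = TRUE,
                    prob = config$regimen_class_probs)

  d <- config$adherence_dist
  from_high <- stats::runif(n) < d$mix_weight
  propensity <- ifelse(
    from_high,
    stats::rbeta(n, d$mean_high * d$conc_high, (1 - d$mean_high) * d$conc_high),
    stats::rbeta(n, d$mean_low * d$conc_low, (1 - d$mean_low) * d$conc_low)
  )

  taken_doses <- stats::rbinom(n, total_doses, propensity)
  true_adherence <- taken_doses / total_doses
  taken_pills <- taken_doses * pills_per_dose
  missed_pills <- total_pills - taken_pills

  # self-report channel
  sr_missed <- round(missed_pills * config$sr_underreport_factor)
  sr_missed[stats::runif(n) < config$sr_zero_report_prob] <- 0L

  # pharmacy-refill channel
  surplus <- ifelse(stats::runif(n) < config$pr_surplus_prob,
                    sample(1:14, n, replace = TRUE), 0L)
  dispensed_prev <- rep(total_pills, n)
  returned_prev <- surplus
  returned_current <- dispensed_prev + returned_prev - taken_pills
  returned_current[stats::runif(n) < config$pr_unknown_leftover_prob] <- NA_integer_

  # RTMM channel
  recorded <- stats::rbinom(n, taken_doses, 1 - config$rtmm_outage_day_prob)
  pocket_k <- ifelse(stats::runif(n) < config$rtmm_pocket_dose_prob,
                     sample(2:4, n, replace = TRUE), 1L)
  openings <- pmax(recorded - (pocket_k - 1L), 0L)
  if (rtmm_arm_fraction < 1) {
    in_arm <- sample(c(TRUE, FALSE), n, replace = TRUE,
                     prob = c(rtmm_arm_fraction, 1 - rtmm_arm_fraction))
    openings[!in_arm] <- NA_integer_
  }

  vl <- simulate_outcome(true_adherence, regimen == "TLE", config)

  cohort <- tibble::tibble(
    participant_id = sprintf("P%04d", seq_len(n)),
    sex = sex,
    regimen_class = regimen,
    true_adherence = true_adherence,
    pills_per_day = as.integer(ppd),
    days_in_window = as.integer(days),
    dosing_moments_per_day = as.integer(moments),
    sr_missed_pills = as.integer(sr_missed),
    pr_dispensed_prev = as.integer(dispensed_prev),
    pr_returned_prev = as.integer(returned_prev),
    pr_returned_current = as.integer(returned_current),
    rtmm_openings = as.integer(openings),
    rtmm_expected_openings = as.integer(total_doses),
    vl_detectable = vl
  )
  validate_cohort(cohort)
}

#' Draw virological outcomes from the logistic outcome model
#'
#' Bernoulli draw of a detectable viral load with log-odds
#' `outcome_intercept + outcome_slope * true_adherence +
#' outcome_tle_effect * is_tle`. Uses R's current RNG state; seed the
#' stream (or call via [simulate_cohort()]) for reproducibility.
#'
#' @param true_adherence Adherence fraction(s) in \[0, 1\].
#' @param is_tle Logical, recycled: on a TLE regimen?
#' @param config A [sim_config()] supplying the outcome parameters.
#' @return Logical vector of detectable-viral-load indicators.
#' @export
simulate_outcome <- function(true_adherence, is_tle, config) {
  if (any(is.na(true_adherence)) || any(true_adherence < 0 | true_adherence > 1))
    stop("`true_adherence` must be in [0, 1]", call. = FALSE)
  p <- stats::plogis(config$outcome_intercept +
                       config$outcome_slope * true_adherence +
                       config$outcome_tle_effect * as.numeric(is_tle))
  stats::runif(length(true_adherence)) < p
}

cohort_columns <- c(
  "participant_id", "sex", "regimen_class", "true_adherence",
  "pills_per_day", "days_in_window", "dosing_moments_per_day",
  "sr_missed_pills", "pr_dispensed_prev", "pr_returned_prev",
  "pr_returned_current", "rtmm_openings", "rtmm_expected_openings",
  "vl_detectable"
)

#' Validate a cohort table against the record invariants
#'
#' Checks column presence and per-row invariants (self-reported missed
#' pills cannot exceed the prescription, pharmacy counts are non-negative,
#' expected openings match the dosing schedule). Errors name the first
#' offending row.
#'
#' @param cohort A cohort tibble as produced by [simulate_cohort()] or
#'   [read_cohort()].
#' @return The cohort, unchanged, for piping.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  fail_row <- function(cond, msg) {
    bad <- which(cond)
    if (length(bad) > 0)
      stop(sprintf("cohort invariant violated at row %d: %s", bad[1], msg),
           call. = FALSE)
  }
  total_pills <- cohort$days_in_window * cohort$pills_per_day
  fail_row(cohort$sr_missed_pills > total_pills | cohort$sr_missed_pills < 0,
           "sr_missed_pills must be in [0, days_in_window * pills_per_day]")
  fail_row(cohort$pr_dispensed_prev < 0 | cohort$pr_returned_prev < 0,
           "pharmacy counts must be non-negative")
  fail_row(!is.na(cohort$pr_returned_current) & cohort$pr_returned_current < 0,
           "pr_returned_current must be non-negative when known")
  fail_row(!is.na(cohort$rtmm_openings) & cohort$rtmm_openings < 0,
           "rtmm_openings must be non-negative")
  fail_row(cohort$rtmm_expected_openings !=
             cohort$days_in_window * cohort$dosing_moments_per_day,
           "rtmm_expected_openings must equal days_in_window * dosing_moments_per_day")
  fail_row(!cohort$sex %in% c("female", "male"), "sex must be female or male")
  fail_row(!is.na(cohort$true_adherence) &
             (cohort$true_adherence < 0 | cohort$true_adherence > 1),
           "true_adherence must be in [0, 1]")
  cohort
}

#' Write or read a cohort as CSV
#'
#' The CSV has a fixed header (one row per participant); unknown leftover
#' counts and absent RTMM data are encoded as empty fields. `read_cohort()`
#' validates the record invariants after parsing and reports the row number
#' of any malformed entry.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the validated cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort[, cohort_columns], path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  spec <- readr::cols(
    participant_id = readr::col_character(),
    sex = readr::col_character(),
    regimen_class = readr::col_character(),
    true_adherence = readr::col_character(),
    pills_per_day = readr::col_integer(),
    days_in_window = readr::col_integer(),
    dosing_moments_per_day = readr::col_integer(),
    sr_missed_pills = readr::col_integer(),
    pr_dispensed_prev = readr::col_integer(),
    pr_returned_prev = readr::col_integer(),
    pr_returned_current = readr::col_integer(),
    rtmm_openings = readr::col_integer(),
    rtmm_expected_openings = readr::col_integer(),
    vl_detectable = readr::col_logical()
  )
  cohort <- readr::read_csv(path, col_types = spec, na = "")
  # base R's decimal parser round-trips shortest representations exactly
  cohort$true_adherence <- as.numeric(cohort$true_adherence)
  probs <- readr::problems(cohort)
  if (nrow(probs) > 0)
    stop(sprintf("malformed cohort CSV at row %d: expected %s, got %s",
                 probs$row[1], probs$expected[1], probs$actual[1]),
         call. = FALSE)
  validate_cohort(cohort)
}
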