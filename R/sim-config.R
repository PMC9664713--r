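#' Simulation configuration for a synthetic adherence cohort
#'
#' Bundles every generative parameter of the synthetic cohort: cohort
#' composition, the latent adherence mixture, the visit-window dosing
#' schedule, the virological-outcome model and the measurement-error
#' mechanisms of the three adherence channels.
#'
#' The latent adherence distribution is a two-component beta mixture on
#' \[0, 1\]: an *adherent* component (high mean, high concentration) and a
#' *struggling* component (lower mean, more spread). Each component is
#' parameterized by its mean \eqn{\mu} and concentration \eqn{\kappa}
#' (shape parameters \eqn{\mu\kappa} and \eqn{(1-\mu)\kappa}); `mix_weight`
#' is the probability of the adherent component. A bimodal latent law keeps
#' participants on both sides of every cut-off in the 80--100% grid, which a
#' single high-mean distribution would not.
#'
#' The outcome model is logistic: the probability of a detectable week-48
#' viral load is `plogis(outcome_intercept + outcome_slope * adherence +
#' outcome_tle_effect * is_tle)`, where `adherence` is the realized intake
#' fraction. Defaults are calibrated so the expected detectable fraction is
#' about 0.31 with about 70% of the cohort female, matching a typical
#' ART-experienced cohort selected for suspected nonadherence.
#'
#' Measurement-error mechanisms:
#' * `sr_zero_report_prob` — probability a participant reports zero missed
#'   pills regardless of the truth (social desirability).
#' * `sr_underreport_factor` — multiplicative shrinkage in \[0, 1\] applied
#'   to the true missed-dose count before it is reported.
#' * `pr_unknown_leftover_prob` — probability the returned-pill count at the
#'   current visit is unavailable (participant did not bring leftovers and
#'   cannot recall them).
#' * `pr_surplus_prob` — probability the previous dispensing carried a
#'   surplus beyond the window's prescription.
#' * `rtmm_outage_day_prob` — per-dose probability that an actual intake
#'   produces no device-opening record (battery/connectivity outage).
#' * `rtmm_pocket_dose_prob` — per-window probability that the participant
#'   removes several doses in a single opening ("pocket dosing"), so the
#'   device undercounts intake.
#'
#' @param n_participants Number of participants (default 233).
#' @param prop_female Probability a participant is female (default 0.704).
#' @param regimen_class_probs Named probabilities over regimen classes
#'   `TLE`, `other_first_line`, `PI_based`, `DTG_based`; must sum to 1.
#' @param adherence_dist Named list with `mean_high`, `conc_high`,
#'   `mean_low`, `conc_low`, `mix_weight` describing the beta mixture.
#' @param days_in_window Length of the final inter-visit window in days
#'   (default 56, a two-monthly visit schedule).
#' @param pills_per_day Prescribed pills per day (default 1).
#' @param dosing_moments_per_day Dosing moments per day (default 1); must
#'   divide `pills_per_day`.
#' @param outcome_intercept,outcome_slope,outcome_tle_effect Log-odds scale
#'   parameters of the outcome model (slope is per unit adherence fraction;
#'   negative means higher adherence lowers failure odds).
#' @param sr_zero_report_prob,sr_underreport_factor Self-report error
#'   mechanism (see Details).
#' @param pr_unknown_leftover_prob,pr_surplus_prob Pharmacy-refill error
#'   mechanism (see Details).
#' @param rtmm_outage_day_prob,rtmm_pocket_dose_prob RTMM error mechanism
#'   (see Details).
#' @param seed Integer seed; the same config (including seed) reproduces a
#'   byte-identical cohort.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_cohort()], [read_sim_config()]
#' @examples
#' cfg <- sim_config(n_participants = 50, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' @export
sim_config <- function(n_participants = 233,
                       prop_female = 0.704,
                       regimen_class_probs = c(TLE = 0.32,
                                               other_first_line = 0.32,
                                               PI_based = 0.20,
                                               DTG_based = 0.16),
                       adherence_dist = list(mean_high = 0.95,
                                             conc_high = 40,
                                             mean_low = 0.65,
                                             conc_low = 8,
                                             mix_weight = 0.65),
                       days_in_window = 56,
                       pills_per_day = 1,
                       dosing_moments_per_day = 1,
                       outcome_intercept = 2.75,
                       outcome_slope = -4,
                       outcome_tle_effect = -0.8,
                       sr_zero_report_prob = 0.5,
                       sr_underreport_factor = 0.5,
                       pr_unknown_leftover_prob = 0.2,
                       pr_surplus_prob = 0.1,
                       rtmm_outage_day_prob = 0.02,
                       rtmm_pocket_dose_prob = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_participants = n_participants,
    prop_female = prop_female,
    regimen_class_probs = regimen_class_probs,
    adherence_dist = adherence_dist,
    days_in_window = days_in_window,
    pills_per_day = pills_per_day,
    dosing_moments_per_day = dosing_moments_per_day,
    outcome_intercept = outcome_intercept,
    outcome_slope = outcome_slope,
    outcome_tle_effect = outcome_tle_effect,
    sr_zero_report_prob = sr_zero_report_prob,
    sr_underreport_factor = sr_underreport_factor,
    pr_unknown_leftover_prob = pr_unknown_leftover_prob,
    pr_surplus_prob = pr_surplus_prob,
    rtmm_outage_day_prob = rtmm_outage_day_prob,
    rtmm_pocket_dose_prob = rtmm_pocket_dose_prob,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

regimen_levels <- c("TLE", "other_first_line", "PI_based", "DTG_based")

#' Validate a simulation configuration
#'
#' Checks every field of a [sim_config()] object; errors name the offending
#' field so configuration mistakes surface immediately rather than as
#' malformed cohorts.
#'
#' @param cfg A `sim_config` object or a plain named list with its fields.
#' @return The validated `sim_config`, invisibly usable in pipelines.
#' @export
validate_sim_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid sim_config field `%s`: %s", field, msg), call. = FALSE)
  }
  chk_prob <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop_field(field, "must be a single probability in [0, 1]")
  }
  chk_count <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != round(x))
      stop_field(field, "must be a single positive integer")
  }

  chk_count("n_participants")
  chk_count("days_in_window")
  chk_count("pills_per_day")
  chk_count("dosing_moments_per_day")
  if (cfg$pills_per_day %% cfg$dosing_moments_per_day != 0)
    stop_field("dosing_moments_per_day", "must divide pills_per_day")

  chk_prob("prop_female")
  for (f in c("sr_zero_report_prob", "sr_underreport_factor",
              "pr_unknown_leftover_prob", "pr_surplus_prob",
              "rtmm_outage_day_prob", "rtmm_pocket_dose_prob"))
    chk_prob(f)

  p <- cfg$regimen_class_probs
  if (!is.numeric(p) || is.null(names(p)) || !setequal(names(p), regimen_levels))
    stop_field("regimen_class_probs",
               paste("must be named probabilities over",
                     paste(regimen_levels, collapse = ", ")))
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop_field("regimen_class_probs", "must be non-negative and sum to 1")

  d <- cfg$adherence_dist
  need <- c("mean_high", "conc_high", "mean_low", "conc_low", "mix_weight")
  if (!is.list(d) || !all(need %in% names(d)))
    stop_field("adherence_dist", paste("must contain", paste(need, collapse = ", ")))
  for (f in c("mean_high", "mean_low", "mix_weight")) {
    x <- d[[f]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop_field(paste0("adherence_dist$", f), "must be in [0, 1]")
  }
  for (f in c("conc_high", "conc_low")) {
    x <- d[[f]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
      stop_field(paste0("adherence_dist$", f), "must be positive")
  }

  for (f in c("outcome_intercept", "outcome_slope", "outcome_tle_effect")) {
    x <- cfg[[f]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
      stop_field(f, "must be a single finite number")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    stop_field("seed", "must be a single integer")

  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  n_participants: %d, prop_female: %.3f, seed: %d\n",
              x$n_participants, x$prop_female, x$seed))
  cat(sprintf("  window: %d days x %d pill(s)/day (%d dosing moment(s))\n",
              x$days_in_window, x$pills_per_day, x$dosing_moments_per_day))
  d <- x$adherence_dist
  cat(sprintf("  adherence mixture: %.2f Beta(mean %.2f, conc %g) + %.2f Beta(mean %.2f, conc %g)\n",
              d$mix_weight, d$mean_high, d$conc_high,
              1 - d$mix_weight, d$mean_low, d$conc_low))
  cat(sprintf("  outcome log-odds: %.3g %+.3g*adherence %+.3g*TLE\n",
              x$outcome_intercept, x$outcome_slope, x$outcome_tle_effect))
  cat(sprintf("  SR errors: zero-report %.2f, underreport factor %.2f\n",
              x$sr_zero_report_prob, x$sr_underreport_factor))
  cat(sprintf("  PR errors: unknown leftover %.2f, surplus %.2f\n",
              x$pr_unknown_leftover_prob, x$pr_surplus_prob))
  cat(sprintf("  RTMM errors: outage/day %.3f, pocket dosing %.2f\n",
              x$rtmm_outage_day_prob, x$rtmm_pocket_dose_prob))
  invisible(x)
}

#' Read or write a simulation configuration as YAML/JSON
#'
#' `read_sim_config()` accepts a YAML (or JSON, which YAML subsumes) file
#' holding any subset of [sim_config()] fields; unspecified fields take
#' their defaults, and the result is validated.
#'
#' @param path File path.
#' @return For `read_sim_config()`, a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$regimen_class_probs))
    raw$regimen_class_probs <- unlist(raw$regimen_class_probs)
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param cfg A `sim_config` object.
#' @export
write_sim_config <- function(cfg, path) {
  cfg <- validate_sim_config(cfg)
  out <- unclass(cfg)
  out$regimen_class_probs <- as.list(out$regimen_class_probs)
  yaml::write_yaml(out, path)
  invisible(path)
}
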