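# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: pair counting instead of the trapezoid, direct
# likelihood search instead of IRLS, numeric integration instead of
# Monte Carlo.

# Mann-Whitney AUC by exhaustive case-control pair counting, ties = 1/2.
# Orientation: low score predicts a positive (detectable) outcome.
auc_pair_oracle <- function(scores, outcomes) {
  cases <- scores[outcomes]
  controls <- scores[!outcomes]
  total <- 0
  for (s in cases)
    total <- total + sum(s < controls) + 0.5 * sum(s == controls)
  total / (length(cases) * length(controls))
}

# Brute-force 2x2 tally by explicit row loop.
confusion_oracle <- function(flags, outcomes) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(flags)) {
    if (flags[i] == "nonadherent" && outcomes[i]) tp <- tp + 1
    if (flags[i] == "nonadherent" && !outcomes[i]) fp <- fp + 1
    if (flags[i] == "adherent" && outcomes[i]) fn <- fn + 1
    if (flags[i] == "adherent" && !outcomes[i]) tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Expected detectable-outcome prevalence under a sim_config, by numeric
# integration over the adherence mixture and the binomial intake count.
prevalence_oracle <- function(cfg) {
  d <- cfg$adherence_dist
  n_doses <- cfg$days_in_window * cfg$dosing_moments_per_day
  p_tle <- unname(cfg$regimen_class_probs["TLE"])
  dens <- function(a) {
    d$mix_weight * dbeta(a, d$mean_high * d$conc_high,
                         (1 - d$mean_high) * d$conc_high) +
      (1 - d$mix_weight) * dbeta(a, d$mean_low * d$conc_low,
                                 (1 - d$mean_low) * d$conc_low)
  }
  inner <- function(a) {
    vapply(a, function(ai) {
      t <- 0:n_doses
      w <- dbinom(t, n_doses, ai)
      frac <- t / n_doses
      eta <- cfg$outcome_intercept + cfg$outcome_slope * frac
      sum(w * ((1 - p_tle) * plogis(eta) +
                 p_tle * plogis(eta + cfg$outcome_tle_effect)))
    }, 0)
  }
  stats::integrate(function(a) dens(a) * inner(a), 0, 1,
                   subdivisions = 500)$value
}

# Direct likelihood maximization for logistic regression, independent of
# IRLS: Nelder-Mead/BFGS on the hand-written binomial log-likelihood.
logistic_mle_oracle <- function(x, y) {
  negll <- function(beta) {
    eta <- drop(x %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- stats::optim(rep(0, ncol(x)), negll, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-14))
  fit$par
}

# A config with every measurement-error mechanism switched off.
error_free_config <- function(...) {
  sim_config(sr_zero_report_prob = 0, sr_underreport_factor = 1,
             pr_unknown_leftover_prob = 0, pr_surplus_prob = 0,
             rtmm_outage_day_prob = 0, rtmm_pocket_dose_prob = 0, ...)
}
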