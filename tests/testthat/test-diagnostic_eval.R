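test_that("confusion counts match hand enumeration and a brute-force tally", {
  cc <- confusion(c("nonadherent", "adherent", "nonadherent", "adherent"),
                  c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cc[c("tp", "fn", "fp", "tn")],
               list(tp = 1, fn = 1, fp = 1, tn = 1))

  cc <- confusion(rep("adherent", 6), rep(FALSE, 6))
  expect_equal(cc[c("tp", "fp", "fn", "tn")],
               list(tp = 0, fp = 0, fn = 0, tn = 6))

  set.seed(50)
  flags <- sample(c("adherent", "nonadherent"), 50, replace = TRUE)
  outcomes <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  expect_equal(confusion(flags, outcomes)[c("tp", "fp", "fn", "tn")],
               confusion_oracle(flags, outcomes))
  expect_error(confusion(flags, outcomes[-1]), "equal length")
  expect_error(confusion(flags, c(outcomes[-1], NA)), "missing")
})

test_that("metrics use the stated definitions, undefined on zero denominators", {
  m <- diagnostic_metrics(list(tp = 10, fn = 5, fp = 0, tn = 0))
  expect_equal(m$sensitivity, 100 * 10 / 15)
  expect_equal(m$ppv, 100)
  expect_true(is.na(m$specificity)) # no condition-negative participants
  m <- diagnostic_metrics(list(tp = 0, fn = 0, fp = 3, tn = 7))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$npv) == FALSE)
  expect_equal(m$specificity, 70)
})

test_that("ROC vertices match a hand-enumerated threshold sweep", {
  # cases score {97, 85}, controls {99, 90}
  curve <- roc_curve(c(97, 85, 99, 90), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(curve$points$threshold, c(-Inf, 85, 90, 97, 99))
  expect_equal(curve$points$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(curve$points$tpr, c(0, 0.5, 0.5, 1, 1))
  expect_equal(curve$auc, 0.75) # pairs: 1 + 0 + 1 + 1 of 4
  expect_equal(curve$auc, auc_pair_oracle(c(97, 85, 99, 90),
                                          c(TRUE, TRUE, FALSE, FALSE)))
})

test_that("ROC endpoints, monotonicity and tie collapsing hold", {
  set.seed(60)
  scores <- sample(seq(0, 100, by = 2.5), 120, replace = TRUE) # forces ties
  outcomes <- sample(c(TRUE, FALSE), 120, replace = TRUE)
  curve <- roc_curve(scores, outcomes)
  pts <- curve$points
  expect_equal(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
  expect_equal(c(pts$fpr[nrow(pts)], pts$tpr[nrow(pts)]), c(1, 1))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_equal(nrow(pts), length(unique(scores)) + 1)

  expect_error(roc_curve(scores, rep(TRUE, 120)), "negative")
  expect_error(roc_curve(scores, rep(FALSE, 120)), "positive")
})

test_that("degenerate ROC shapes behave: perfect separation and no information", {
  curve <- roc_curve(c(0, 0, 100, 100), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(curve$auc, 1)
  expect_true(any(curve$points$fpr == 0 & curve$points$tpr == 1))
  expect_equal(as.numeric(optimal_cutoff(curve)), 0) # the separating threshold

  flat <- roc_curve(rep(50, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(nrow(flat$points), 2)
  expect_equal(flat$auc, 0.5)
  expect_true(is.na(optimal_cutoff(flat)))
})

test_that("trapezoidal AUC equals pair counting to 1e-12 on random cohorts", {
  set.seed(70)
  for (rep in 1:100) {
    n <- sample(10:200, 1)
    scores <- round(runif(n, 0, 100), sample(c(0, 1, 2), 1))
    outcomes <- c(TRUE, FALSE,
                  sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(auc(scores, outcomes), auc_pair_oracle(scores, outcomes),
                 tolerance = 1e-12)
  }
})

test_that("AUC respects relabeling and threshold-shift invariances", {
  set.seed(80)
  scores <- runif(80, 60, 100)
  outcomes <- sample(c(TRUE, FALSE), 80, replace = TRUE)
  expect_equal(auc(scores, outcomes), 1 - auc(scores, !outcomes),
               tolerance = 1e-12)
  shifted <- scores - 40
  expect_equal(auc(scores, outcomes), auc(shifted, outcomes), tolerance = 1e-12)
  expect_equal(roc_curve(scores, outcomes)$points[c("fpr", "tpr")],
               roc_curve(shifted, outcomes)$points[c("fpr", "tpr")])
})

test_that("empirical AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(90)
  scores <- round(runif(150, 40, 100), 1)
  outcomes <- sample(c(TRUE, FALSE), 150, replace = TRUE)
  reference <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(outcomes, scores, direction = ">")))
  )
  expect_equal(auc(scores, outcomes), reference, tolerance = 1e-10)
})

test_that("optimal cutoff minimizes distance to the top-left corner", {
  set.seed(100)
  for (rep in 1:20) {
    scores <- round(runif(20, 0, 100), 1)
    outcomes <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 18, replace = TRUE))
    curve <- roc_curve(scores, outcomes)
    if (nrow(curve$points) <= 2) next
    interior <- curve$points[-c(1, nrow(curve$points)), ]
    dists <- sqrt(interior$fpr^2 + (1 - interior$tpr)^2)
    best <- optimal_cutoff(curve)
    expect_equal(attr(best, "distance"), min(dists), tolerance = 1e-12)
    expect_true(as.numeric(best) %in%
                  interior$threshold[abs(dists - min(dists)) < 1e-12])
  }
})

test_that("optimal-cutoff ties break toward higher sensitivity then lower threshold", {
  # two vertices equidistant from (0, 1): (0, 0.5) at threshold 10 and
  # (0.5, 1) at threshold 30
  scores <- c(10, 30, 30, 50)
  outcomes <- c(TRUE, TRUE, FALSE, FALSE)
  curve <- roc_curve(scores, outcomes)
  best <- optimal_cutoff(curve)
  expect_equal(as.numeric(best), 30)
  expect_equal(attr(best, "sensitivity"), 100)
})

test_that("diagnostic_table evaluates every measure-cutoff cell", {
  panel <- build_panel(simulate_cohort(sim_config(n_participants = 100, seed = 6)))
  tab <- diagnostic_table(panel, measures = "sr")
  expect_equal(nrow(tab), 5)
  full <- diagnostic_table(panel)
  expect_equal(nrow(full), 25)
  expect_true(all(full$tp + full$fp + full$fn + full$tn == full$n))
  percents <- unlist(full[c("sensitivity", "specificity", "ppv", "npv")])
  expect_true(all(is.na(percents) | (percents >= 0 & percents <= 100)))
})

test_that("a perfectly separating measure gets sens = spec = 100 at its cutoff", {
  panel <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:10),
    sr_adherence = c(rep(70, 4), rep(95, 6)),
    pr_adherence = 100, rtmm_adherence = 100,
    vl_detectable = c(rep(TRUE, 4), rep(FALSE, 6)),
    sex = "female", regimen_class = "TLE"
  )
  row <- dplyr::filter(diagnostic_table(panel, measures = "sr"), cutoff == 90)
  expect_equal(row$sensitivity, 100)
  expect_equal(row$specificity, 100)
})

test_that("strong self-report over-reporting lowers SR sensitivity, raises specificity", {
  cfg <- sim_config(n_participants = 600, seed = 123,
                    sr_zero_report_prob = 0.5, sr_underreport_factor = 0.5,
                    rtmm_outage_day_prob = 0.02)
  tab <- diagnostic_table(build_panel(simulate_cohort(cfg)),
                          measures = c("sr", "pr", "rtmm"))
  wide <- tidyr::pivot_wider(tab[c("measure", "cutoff", "sensitivity", "specificity")],
                             names_from = "measure",
                             values_from = c("sensitivity", "specificity"))
  expect_true(all(wide$sensitivity_sr <= pmin(wide$sensitivity_pr,
                                              wide$sensitivity_rtmm)))
  expect_true(all(wide$specificity_sr >= pmax(wide$specificity_pr,
                                              wide$specificity_rtmm)))
})

test_that("measures with no observations raise a usage error", {
  panel <- build_panel(simulate_cohort(sim_config(n_participants = 30, seed = 8),
                                       rtmm_arm_fraction = 0))
  expect_error(diagnostic_table(panel, measures = "rtmm"), "absent")
  expect_error(diagnostic_table(panel[0, ], measures = "sr"), "empty")
})

test_that("disposition percentages recompute from nested counts", {
  d <- disposition_summary(249, 233, 161)
  expect_equal(d$completed_pct, 100 * 233 / 249)
  expect_equal(d$suppressed_pct, 100 * 161 / 233)
  expect_equal(d$detectable_pct, 100 * 72 / 233)
  expect_error(disposition_summary(100, 120, 50), "nested")
})
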