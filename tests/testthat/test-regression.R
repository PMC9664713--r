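test_that("encode_design produces the documented indicator coding", {
  panel <- tibble::tibble(
    participant_id = "P1", sr_adherence = 90, pr_adherence = 100,
    rtmm_adherence = 100, vl_detectable = TRUE,
    sex = "female", regimen_class = "TLE"
  )
  d <- encode_design(panel, "sr", 95)
  expect_equal(unname(d$x[1, ]), c(1, 1, 0, 1)) # nonadherent, female, TLE
  expect_equal(colnames(d$x), c("(Intercept)", "nonadherent", "male", "tle"))

  panel2 <- tibble::tibble(
    participant_id = c("P1", "P2"),
    sr_adherence = c(100, 80), pr_adherence = 100,
    rtmm_adherence = c(NA_real_, NA_real_),
    vl_detectable = c(TRUE, FALSE),
    sex = c("male", "female"), regimen_class = c("PI_based", "TLE")
  )
  d2 <- encode_design(panel2, "sr", 90)
  expect_equal(unname(d2$x[, "nonadherent"]), c(0, 1))
  expect_equal(unname(d2$x[, "male"]), c(1, 0))
  expect_equal(unname(d2$x[, "tle"]), c(0, 1))
  expect_error(encode_design(panel2, "rtmm", 90), "absent")
  expect_error(encode_design(panel2, "sr", 0), "cutoff")
})

test_that("encode_design matches a hand-built matrix on a 10-row panel", {
  set.seed(110)
  panel <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:10),
    sr_adherence = round(runif(10, 60, 100)),
    pr_adherence = 100, rtmm_adherence = 100,
    vl_detectable = sample(c(TRUE, FALSE), 10, replace = TRUE),
    sex = sample(c("female", "male"), 10, replace = TRUE),
    regimen_class = sample(c("TLE", "PI_based"), 10, replace = TRUE)
  )
  d <- encode_design(panel, "sr", 90)
  hand <- cbind(1, as.numeric(panel$sr_adherence < 90),
                as.numeric(panel$sex == "male"),
                as.numeric(panel$regimen_class == "TLE"))
  expect_equal(unname(d$x), hand)
  expect_equal(d$y, panel$vl_detectable)
})

test_that("intercept-only fit reproduces the closed-form log-odds of prevalence", {
  x <- matrix(1, nrow = 100, dimnames = list(NULL, "(Intercept)"))
  y <- rep(c(TRUE, FALSE), c(30, 70))
  fit <- fit_logistic(x, y)
  expect_equal(fit$terms$estimate, log(30 / 70), tolerance = 1e-8)
  expect_equal(fit$terms$odds_ratio, 30 / 70, tolerance = 1e-8)
})

test_that("a symmetric design with outcome independent of predictor gives slope 0", {
  x <- cbind(`(Intercept)` = 1, exposed = rep(c(0, 1), each = 40))
  y <- rep(c(TRUE, FALSE, TRUE, FALSE), each = 20)
  fit <- fit_logistic(x, y)
  slope <- fit$terms$estimate[fit$terms$term == "exposed"]
  expect_equal(slope, 0, tolerance = 1e-8)
})

test_that("IRLS estimates match a direct likelihood search on a 20-row fixture", {
  set.seed(120)
  x <- cbind(`(Intercept)` = 1,
             nonadherent = rep(c(0, 1), 10),
             male = sample(c(0, 1), 20, replace = TRUE))
  eta <- -0.5 + 1.2 * x[, "nonadherent"] - 0.4 * x[, "male"]
  y <- runif(20) < plogis(eta)
  if (all(y) || !any(y)) y[1:2] <- c(TRUE, FALSE)
  fit <- fit_logistic(x, y)
  oracle <- logistic_mle_oracle(x, as.numeric(y))
  expect_equal(fit$terms$estimate, unname(oracle), tolerance = 1e-4)
})

test_that("Wald inference is internally consistent", {
  panel <- build_panel(simulate_cohort(sim_config(n_participants = 300, seed = 19)))
  fit <- fit_logistic(encode_design(panel, "pr", 90))
  t <- fit$terms
  expect_equal(t$odds_ratio, exp(t$estimate))
  expect_true(all(t$conf_low < t$conf_high))
  expect_true(all(t$p_value >= 0 & t$p_value <= 1))
  expect_equal(t$conf_low, exp(t$estimate - qnorm(0.975) * t$std_error))
})

test_that("separation is flagged with a warning, not silently repaired", {
  x <- cbind(`(Intercept)` = 1, exposed = rep(c(0, 1), each = 10))
  y <- rep(c(FALSE, TRUE), each = 10) # complete separation
  expect_warning(fit <- fit_logistic(x, y), "separation")
  expect_true(fit$separation)
  expect_gt(abs(fit$terms$estimate[2]), 8)
  # the Firth option keeps the estimate finite on the same data
  firth <- fit_logistic(x, y, method = "firth")
  expect_false(firth$separation)
  expect_lt(abs(firth$terms$estimate[2]), 8)
  expect_true(firth$converged)
})

test_that("fit is invariant to row order and participant relabeling", {
  panel <- build_panel(simulate_cohort(sim_config(n_participants = 200, seed = 23)))
  fit1 <- fit_logistic(encode_design(panel, "sr", 95))
  shuffled <- panel[sample(nrow(panel)), ]
  shuffled$participant_id <- sprintf("Q%04d", seq_len(nrow(shuffled)))
  fit2 <- fit_logistic(encode_design(shuffled, "sr", 95))
  expect_equal(fit1$terms, fit2$terms, tolerance = 1e-10)
})

test_that("fit_logistic rejects degenerate inputs", {
  x <- cbind(`(Intercept)` = 1, flat = rep(1, 10))
  expect_error(fit_logistic(x, rep(c(TRUE, FALSE), 5)), "constant")
  x2 <- matrix(1, nrow = 10, dimnames = list(NULL, "(Intercept)"))
  expect_error(fit_logistic(x2, rep(TRUE, 10)), "both outcome classes")
})

test_that("regression_sweep fits one adjusted model per measure-cutoff cell", {
  panel <- build_panel(simulate_cohort(sim_config(n_participants = 250, seed = 29)))
  fits <- suppressWarnings(regression_sweep(panel, measures = c("sr", "pr", "rtmm")))
  cells <- dplyr::distinct(fits, measure, cutoff)
  expect_equal(nrow(cells), 15)
  expect_setequal(unique(fits$term), c("(Intercept)", "nonadherent", "male", "tle"))
  # failed cells are recorded, not fatal: poison one measure
  panel$pr_adherence <- 100 # nonadherent indicator becomes constant
  fits2 <- suppressWarnings(regression_sweep(panel, measures = c("sr", "pr")))
  failures <- attr(fits2, "failures")
  expect_equal(nrow(failures), 5)
  expect_true(all(failures$measure == "pr"))
  expect_equal(nrow(dplyr::distinct(fits2, measure, cutoff)), 5)
})

test_that("the generative TLE effect sign is recovered on large cohorts", {
  hits <- 0
  for (seed in 1:25) {
    cfg <- sim_config(n_participants = 2000, outcome_tle_effect = -0.8,
                      seed = 300 + seed)
    panel <- build_panel(simulate_cohort(cfg))
    fit <- suppressWarnings(fit_logistic(encode_design(panel, "pr", 90)))
    est <- fit$terms$estimate[fit$terms$term == "tle"]
    hits <- hits + (est < 0)
  }
  expect_gte(hits, 24) # sign recovered in >95% of replicates
})
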