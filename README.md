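# adheval

Evaluate how well routine medication-adherence measures predict
virological failure in people living with HIV on antiretroviral therapy
(ART).

Clinics monitor ART adherence through three imperfect instruments:
**self-report** (SR — "how many pills did you miss?"), **pharmacy refill
counts** (PR — pills dispensed minus pills returned over the inter-visit
interval) and **real-time medication monitoring** (RTMM — an electronic
pill box that records each opening). `adheval` implements the full
evaluation chain for asking whether any of these — alone, SR+PR combined,
or all three combined — screens for a detectable viral load:

* **Scores.** `self_report_adherence()`, `pharmacy_refill_adherence()`
  and `rtmm_adherence()` compute the three percent scales:
  SR = 100·((d·p − missed)/(d·p)); PR = 100·((dispensed + returned_prev −
  returned_cur)/(d·p)), truncated at 100% with unknown leftovers mapped to
  100% by assumption; RTMM = 100·(openings / expected openings), capped.
* **Classification.** `dichotomize()` flags nonadherence strictly below a
  cut-off on the grid {80, 85, 90, 95, 100}%; composites use the
  any-measure union rule (`combine_flags()`), whose continuous analog is
  the per-participant minimum (`composite_score()`).
* **Diagnostic accuracy.** `diagnostic_table()` gives sensitivity,
  specificity, PPV and NPV per (measure, cut-off), with detectable viral
  load (≥ 20 copies/mL by default) as the condition; `roc_curve()` /
  `auc()` build the empirical tie-collapsed ROC (trapezoidal AUC = the
  Mann–Whitney statistic with half-credit ties) and `optimal_cutoff()`
  picks the vertex closest to the top-left corner.
* **Regression.** `fit_logistic()` / `regression_sweep()` fit one
  adjusted logistic model per measure and cut-off (covariates: sex and
  TLE-vs-other regimen), with Wald inference, separation flagging and an
  optional Firth-penalized fit.
* **Synthetic cohorts.** `sim_config()` / `simulate_cohort()` generate a
  trial-shaped cohort (default n = 233, ~70% female, ~31% detectable at
  week 48) from one latent intake stream observed through explicit
  measurement-error mechanisms: self-report over-reporting, unknown
  leftover pills, pocket dosing and device outages.

A thin subcommand CLI over the same functions lives at
`inst/scripts/adheval.R` (`simulate` / `evaluate` / `regress` / `report` /
`all` driven by a YAML config).

## Worked example

```r
library(adheval)

cfg    <- sim_config(n_participants = 233, seed = 1)
cohort <- simulate_cohort(cfg)
panel  <- build_panel(cohort)

diagnostic_table(panel, measures = c("sr", "pr", "sr+pr+rtmm"))[
  , c("measure", "cutoff", "sensitivity", "specificity", "ppv", "npv")]

curves <- roc_curves(panel)
sapply(curves, function(cv) cv$auc)
```

At the 95% cut-off this prints (percents, rounded):

```
  measure     sensitivity specificity  ppv  npv
  sr                 24.4        82.8 43.5 66.8
  pr                 62.2        55.6 43.2 73.0
  sr+pr+rtmm         85.4        29.1 39.5 78.6
```

and the AUCs with closest-to-top-left optimal cut-offs:

```
sr          AUC 0.490  optimal cutoff 92.9%
pr          AUC 0.635  optimal cutoff 89.3%
rtmm        AUC 0.684  optimal cutoff 85.7%
sr+pr       AUC 0.636  optimal cutoff 89.3%
sr+pr+rtmm  AUC 0.684  optimal cutoff 85.7%
```

Read: under the default over-reporting scenario, self-report rarely
catches the participants who go on to fail (lowest sensitivity) but
seldom mislabels the suppressed (highest specificity); combining all
three measures flags most failures at the cost of specificity — the
union rule can only add nonadherent classifications. An adjusted
regression for one cell:

```r
fit_logistic(encode_design(panel, "sr", 95))
#> <logistic_fit> n = 233, method = ml
#>          term estimate std_error odds_ratio conf_low conf_high  p_value
#> 1 (Intercept)  -0.6590    0.2079     0.5174   0.3442    0.7776 0.001526
#> 2 nonadherent   0.3969    0.3386     1.4872   0.7659    2.8877 0.241064
#> 3        male   0.3201    0.2965     1.3772   0.7703    2.4624 0.280272
#> 4         tle  -0.4098    0.2998     0.6638   0.3689    1.1945 0.171592
```

The odds ratio of 1.49 for nonadherence (95% CI 0.77–2.89) illustrates
the typical finding at this sample size: wide intervals, low precision.

The end-to-end pipeline (simulate → score → evaluate → regress → report)
is one call:

```r
cfg <- pipeline_config(cohort_path = "cohort.csv", results_dir = "results")
run_pipeline(cfg)
```

See `vignettes/adherence-evaluation.Rmd` for the models, assumptions,
generator design and numerical choices.

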