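---
title: "Evaluating adherence measures as predictors of detectable viral load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating adherence measures as predictors of detectable viral load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adheval)
```

## The problem

Sustained adherence to antiretroviral therapy (ART) is what keeps HIV
virally suppressed, and clinics in low-resource settings monitor it with
whatever instruments are feasible: asking the patient (self-report, SR),
counting pills against the dispensing ledger (pharmacy refill, PR), or an
electronic pill box that transmits a record of each opening (real-time
medication monitoring, RTMM). Each channel observes the same underlying
intake behaviour through a different error mechanism, and none of them
observes it cleanly. The question this package operationalizes is a
screening question: *how well does each measure — alone or combined —
predict a detectable viral load at the end of follow-up, and at which
adherence cut-off is that prediction strongest?*

`adheval` provides the full evaluation chain as composable, tested
functions: adherence scoring from raw observables, dichotomization on a
cut-off grid, any-measure composites, confusion-matrix accuracy metrics,
empirical ROC/AUC analysis with an optimal cut-off rule, and
covariate-adjusted logistic regression — plus a synthetic cohort generator
so the whole chain can be exercised and validated without patient data.

## Adherence scores

All three scores live on a percent scale in $[0, 100]$.

**Self-report.** With $d$ days in the recall window, $p$ prescribed pills
per day and $m$ reported missed pills,
$$\mathrm{SR} = 100 \times \frac{dp - m}{dp}.$$
The interview asks about "the past month", but the analysis window is the
inter-visit period, so `self_report_adherence()` takes the actual window
length; 30 days is the documented fallback when the window is unrecorded.

**Pharmacy refill.** With $D$ pills dispensed at the previous visit,
$R_{prev}$ leftover pills returned then, and $R_{cur}$ returned (or
recalled) now,
$$\mathrm{PR} = 100 \times \frac{(D + R_{prev}) - R_{cur}}{dp},$$
truncated at 100% because the supply can legitimately exceed the
prescription. When $R_{cur}$ is unknown the participant is assumed to have
taken all pills as prescribed, giving exactly 100%. That direct assignment
— rather than setting $R_{cur}=0$ and relying on the cap — matches the
stated assumption even when dispensing does not cover the window.

**RTMM.** With $o$ recorded openings and $d \times k$ expected openings
($k$ dosing moments per day),
$$\mathrm{RTMM} = 100 \times \frac{o}{dk},$$
also capped at 100. Openings can exceed expectations (curiosity openings,
refilling the box), the source formulas state truncation only for PR, and
published analyses do not say how super-100 values were handled; we cap
all three channels uniformly so downstream cut-off logic sees one scale.
This is a design choice of the package, applied uniformly and visible in
the panel output.

## Classification and composites

A participant is *nonadherent* at cut-off $c$ when adherence is strictly
below $c$; equality counts as adherent, so a 100% cut-off flags only
imperfect adherence. The grid defaults to $\{80, 85, 90, 95, 100\}$,
spanning the range from "forgiving modern regimens" (80%) to perfection.

Composites follow the any-measure union rule: nonadherent on the composite
iff nonadherent on *any* component. For ROC analysis a composite needs a
continuous score; `composite_score()` uses the per-participant **minimum**,
which is the unique scalar whose thresholding reproduces the union rule at
every cut-off simultaneously (a property the suite checks exhaustively on
sampled triples). How the continuous combined score was constructed in the
analyses this package emulates is not documented; the minimum is our
inference from the stated classification rule and is recorded here as an
assumption.

Two structural consequences are tested as invariants: the composite's
nonadherent set is the union of the component sets, so composite
sensitivity is at least each component's and composite specificity at most
each component's; and raising the cut-off can only move participants from
adherent to nonadherent.

## Diagnostic accuracy and ROC

Orientation is fixed throughout: the positive *condition* is a detectable
viral load, the positive *test* is a nonadherent classification. So
sensitivity is the share of participants with detectable viral load who
were flagged nonadherent, and PPV is the share of nonadherent
participants whose viral load is detectable. A zero denominator yields an
explicit `NA`, never a number.

`roc_curve()` sweeps every distinct observed adherence value as a
threshold (plus a $-\infty$ origin), with the test "score at or below the
threshold". Tied scores collapse into a single vertex, and the trapezoidal
area under the vertices equals the Mann–Whitney probability that a random
case scores below a random control, counting ties one half — the suite
verifies that identity to $10^{-12}$ against explicit pair counting on
random cohorts up to $n = 200$. The empirical curve is also cross-checked
against an established ROC implementation. No smoothing, no binormal
model, no AUC confidence intervals: the curve is the empirical one.

The *optimal cut-off* is the interior vertex closest (Euclidean distance)
to the perfect corner $(\mathrm{fpr}, \mathrm{tpr}) = (0, 1)$. Ties break
toward the higher-sensitivity vertex, then the lower threshold — a
deliberate bias toward catching failures in a screening context. The
curve's endpoints (flag nobody / flag everybody) are not candidates, so a
two-point degenerate curve returns `NA`.

The viral-load threshold is configurable: detectable is defined
*inclusively* ($\geq$ threshold), with 20 copies/mL as the default (a
modern assay quantification limit) and 1000 copies/mL the programmatic
alternative used by several national guidelines.

## Adjusted logistic regression

Each measure is fitted in its *own* model — the question is which measure
predicts failure, not their joint contribution — with the nonadherence
indicator at the chosen cut-off, a male indicator and a TLE-regimen
indicator (tenofovir + lamivudine + efavirenz versus any other regimen).
Reference levels are female and non-TLE; source analyses do not state
their coding, so we fix and document ours. Estimation is maximum
likelihood via IRLS to gradient tolerance $10^{-8}$; inference is Wald
(standard errors, 95% CIs, two-sided p-values), matching routine
epidemiological reporting.

At high cut-offs a cell of the adherence-by-outcome table can empty out
and the fit approaches (quasi-)complete separation. We *flag* it (any
fitted probability within $10^{-6}$ of 0/1 together with a diverging
coefficient) and warn, but still report the estimates: silently
penalizing would change the estimand. A hand-written Firth-penalized fit
(`method = "firth"`, penalized IRLS with the Jeffreys-prior score
correction) is available for such cells and is off by default.

## What the synthetic cohort emulates

`simulate_cohort()` generates the final inter-visit window of an
ART-experienced cohort selected for suspected nonadherence — the setting
in which this evaluation design arises. One latent behaviour stream feeds
all three channels:

1. A latent adherence *propensity* is drawn from a two-component beta
   mixture — an adherent component and a struggling component. The
   bimodality is deliberate: it puts participants on both sides of every
   cut-off in the grid, where a single high-mean law would make the 80%
   cut-off degenerate.
2. Actual intake is a Bernoulli event per prescribed dosing moment at
   that propensity. The **realized intake fraction** is stored as
   `true_adherence`; with every error mechanism switched off, all three
   channels equal it exactly, which is the calibration invariant the
   suite asserts per participant.
3. Channel errors distort what each instrument records: self-report
   shrinks the true missed count (`sr_underreport_factor`) and, with
   probability `sr_zero_report_prob`, reports zero missed pills outright;
   the pharmacy ledger loses the returned-pill count with probability
   `pr_unknown_leftover_prob` (triggering the 100% assumption) and can
   carry in a dispensing surplus; RTMM loses opening records to outages
   (per-dose `rtmm_outage_day_prob`) and to pocket dosing
   (`rtmm_pocket_dose_prob`: several doses removed in one opening). By
   construction self-report can only over-state and RTMM can only
   under-state the realized intake — the directional bias structure that
   drives the evaluation's qualitative results.
4. The week-48 outcome is Bernoulli with log-odds
   $\beta_0 + \beta_a \cdot \mathrm{adherence} + \beta_t \cdot
   \mathrm{TLE}$.

### Defaults and their rationale

| Parameter | Default | Why |
|---|---|---|
| `n_participants` | 233 | analysed-cohort size of the emulated trial |
| `prop_female` | 0.704 | cohort composition of the emulated trial |
| `regimen_class_probs` | TLE 0.32, other first-line 0.32, PI 0.20, DTG 0.16 | regimen table of the emulated trial, collapsed to four classes |
| `days_in_window` | 56 | two-monthly clinic visits |
| `pills_per_day`, `dosing_moments_per_day` | 1, 1 | once-daily fixed-dose combination, the dominant modern prescription |
| adherence mixture | $0.65\,\mathrm{Beta}(\mu{=}.95,\kappa{=}40) + 0.35\,\mathrm{Beta}(\mu{=}.65,\kappa{=}8)$ | adherent majority plus a struggling minority, plausible for a cohort pre-selected for adherence problems |
| `outcome_intercept/slope/tle_effect` | 2.75, −4, −0.8 | calibrated once by numeric integration so the expected detectable fraction is 0.31, with TLE protective |
| `sr_zero_report_prob`, `sr_underreport_factor` | 0.5, 0.5 | strong social-desirability over-reporting scenario |
| `pr_unknown_leftover_prob`, `pr_surplus_prob` | 0.2, 0.1 | scenario parameters; no published rates exist |
| `rtmm_outage_day_prob`, `rtmm_pocket_dose_prob` | 0.02, 0.1 | scenario parameters; occasional connectivity loss, occasional pocket dosing |

The error-rate defaults are *scenario parameters, not estimates*: no
quantitative rates for pocket dosing, device outages or leftover
recall are published for this setting. They were chosen once, before the
evaluation suite was run, and define the study conditions under which the
package's properties are demonstrated.

### What it does not emulate

No event timestamps, no SMS-reminder feedback on behaviour, no
longitudinal multi-visit trajectories, no informative missingness (the
unknown-leftover and RTMM-arm mechanisms are independent of adherence),
no data-entry or recall noise beyond the stated mechanisms, and no
regimen–adherence correlation. Passing tests therefore demonstrate that
the *analysis machinery* is correct and that the stated error directions
produce the expected qualitative orderings; they do not certify
quantitative accuracy claims about any real cohort.

## Numerical choices and degenerate inputs

* Self-report arithmetic is exact rational arithmetic scaled to percent;
  caps use `pmin`, so no floating-point drift can push a value above 100.
* Cut-off comparison is strict `<`; boundary equality is adherent.
* Missing values propagate explicitly: an unknown leftover becomes 100%
  by assumption *before* the panel is built; a missing RTMM channel makes
  every RTMM-containing measure missing for that participant, which
  automatically restricts those analyses to the monitored arm.
* ROC requires both outcome classes and errors otherwise, naming the
  missing class; `optimal_cutoff()` returns `NA` on a two-point curve.
* IRLS runs to gradient tolerance $10^{-8}$ with a 100-iteration cap;
  non-convergence without separation is an error, never a silent result.
* The generator seeds R's RNG from `config$seed`; identical configs give
  byte-identical cohorts and, downstream, byte-identical pipeline output
  files.

## Problem sizes used in the validation suite

The suite runs the AUC oracle equivalence on 100 random cohorts up to
$n = 200$; the directional self-report bias on 100 simulated cohorts of
$n = 250$; Wald CI coverage on 200 replicates of $n = 2000$; type-I
calibration on 200 null replicates of $n = 400$; and prevalence
calibration against numeric integration at $n = 5000$. These sizes give
Monte-Carlo error small enough for the stated bands while keeping the
whole suite under a minute of compute.

## Known limitations

The evaluation treats the week-48 window as the entire exposure history;
a measure could predict failure through earlier behaviour the window does
not see. The composite minimum is one defensible continuous combined
score, not the only one. Wald inference is first-order and the
separation flag is a diagnostic, not a repair. And the generator's error
mechanisms, while directionally grounded, have made-up magnitudes — any
quantitative statement derived from the defaults describes the scenario,
not a population.
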