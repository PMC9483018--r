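---
title: "Methods: a time-aware MARS early-warning pipeline for ward deterioration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a time-aware MARS early-warning pipeline for ward deterioration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chartward)
```

`chartward` implements, as one coherent and fully tested package, the
computational rule set of an inpatient early-warning system for a General
Internal Medicine (GIM) ward: a synthetic ward simulator, 6-hour-window
feature engineering, a two-stage MARS risk model, PPV/NPV-targeted risk-group
calibration, an alert-suppression state machine, deployment monitoring
metrics, and an hourly replay driver with downtime protocols. This vignette
is the package's own account of the science: the models and their
assumptions, the parameters that matter, the numerical conventions, and what
the synthetic experiments do and do not demonstrate.

## The prediction problem

Each ward encounter is a stay from admission to the first of discharge or a
deterioration event; during training the event composite is death on the
ward, ICU transfer, step-up unit transfer, or palliative transfer, while
reporting distinguishes that composite from the narrower ICU-or-death one.
The model scores every 6-hour window of the stay using only information
available at the window's end, and a deployment assigns each patient, every
hour, to a High / Medium / Low risk group.

## Synthetic cohorts

Hospital EHR data cannot ship with a package, so every experiment runs on a
seeded generator (`simulate_cohort()`) built to reproduce the statistical
features the pipeline's rules depend on:

* **Arrivals and stays.** Poisson admissions (default 11/day) and log-normal
  lengths of stay (default mean 183 h, `sdlog` 0.8). By Little's law the
  implied steady-state census is 11/24 × 183 ≈ 84 concurrent patients,
  consistent with a mid-size GIM service of ~78 beds and ~4,000 admissions a
  year; a property test checks the realized 90-day mean census against this
  oracle.
* **Outcomes.** A categorical draw per encounter, default mix
  `{none 0.88, death 0.04, icu 0.05, stepup 0.02, palliative 0.01}`; the
  event time is the end of the stay.
* **Latent severity.** An hourly Ornstein–Uhlenbeck process (reversion
  θ = 0.15/h, innovation σ = 0.3). Uneventful stays revert around 0.
  Outcome-bound stays revert around +0.6 and acquire a linear ramp over the
  final 48 h, reaching +2.8 at the event. The ramp is the planted,
  recoverable 48-hour early-warning signal; the chronic +0.6 elevation makes
  deteriorating patients look sicker throughout, so whole-stay ("ever")
  discrimination is also possible. These constants are generator design
  choices fixed once, not quantities fitted to any dataset.
* **Observations.** Each feature is sampled at jittered intervals (vitals
  every ~4 h, most labs daily, HbA1c rarely) with value
  `healthy_mean + healthy_sd·(ε + loading·severity)`. The default catalog
  (`default_feature_catalog()`) covers temperature, blood pressures,
  respiratory rate, troponin, HbA1c, random glucose, hemoglobin, basophils
  and ALT, with healthy means near typical ward-population values and signed
  severity loadings (pressures fall, respirations rise).
* **Artifacts.** With probability `artifact_rate` an observation is replaced
  by a physically impossible magnitude — either a canonical extreme for that
  feature (a four-digit body temperature, a five-digit systolic pressure) or
  an order-of-magnitude blow-up — emulating the data-entry errors real
  extracts contain. Only magnitude corruption is modelled; wrong-patient and
  unit-swap errors are out of scope.

What the generator does **not** emulate: case-mix shifts and seasonality,
correlated multi-organ trajectories, informative sampling (sicker patients
being measured more often), free-text notes, and medication signals. Tests
passing on this cohort therefore demonstrate correctness of the pipeline's
computational rules and recoverability of a planted signal — not clinical
performance on real patients.

## Feature engineering

Windows run from the admission timestamp to the first of discharge or the
outcome, in 6-hour steps with a final partial window kept (a live deployment
scores patients mid-window). Within-window duplicates are averaged. Each
feature contributes three columns: the normalized value, a `_measured` flag,
and `_time_since_measured` — 0 when measured in the window, otherwise the
hours from the window end back to the most recent earlier measurement, and
hours since admission when never measured. Missingness is intentionally
informative and these columns are model inputs.

Numeric conventions, fixed here because no external convention binds them:

* **Percentiles** for trimming are linear-interpolation (R type 7) empirical
  quantiles of *measured* training values. Normalization clips to
  [q01, q99] then maps linearly to [0, 1], so artifacts saturate at exactly
  0 or 1 instead of distorting the scale.
* **Degenerate features** (q01 = q99 on training data) normalize to 0.5 with
  a warning.
* **Imputation** is last-observation-carried-forward across a stay's
  windows, then the training-set normalized mean for leading gaps; it is
  idempotent and leaves no missing cells.
* **Exclusions** (training only): stays under 8 h or over 40 days, with
  boundary stays retained (strict inequalities). The upper bound is read as
  days — an 8-to-40-*hour* band would discard most admissions — and is
  configurable. Deployment-mode preprocessing applies no exclusions: a live
  system must score whoever is on the ward.
* **Assay changes** mid-deployment (e.g. a troponin assay switch) are
  handled by a piecewise map of `(effective-from, scale, offset)` entries
  per feature, latest entry winning; the conversion factor is configuration,
  not a constant.

## The two-stage time-aware MARS model

**Stage 1** is classical least-squares MARS, written from first principles
(`fit_mars()`). The forward pass grows reflected hinge pairs
`B_m(x)·max(0, x_j − t)` / `B_m(x)·max(0, t − x_j)`, at each step choosing
the (parent term, variable, knot) triple with the largest residual
sum-of-squares reduction, computed for all candidate knots of a variable at
once by projecting the hinge columns against the current basis. Candidate
knots are the observed values, subsampled to at most `max_knots` quantiles;
a variable appears at most once per term; products are capped at `degree`
variables. Ties break deterministically (earliest parent, lowest variable
index, smallest knot), making fits reproducible. The backward pass deletes
one term at a time — never the intercept — minimizing
`GCV(M) = (RSS/N)/(1 − C(M)/N)²` with `C(M) = M + d·(M − 1)/2`, and returns
the GCV-minimal submodel visited, which by construction never has higher GCV
than the full forward model. Defaults `max_terms = 21`, `degree = 2`,
`d = 3` follow the customary choice for interaction-capable MARS; all are
exposed. A least-squares fit to 0/1 labels is intentional — the second stage
supplies the probability link.

**Stage 2** converts each encounter's stage-1 score timeline into four
features per window — current score, baseline (admission-window) score,
change from the previous window, change since baseline — and fits a logistic
layer. "Baseline" is defined as the window-0 score: with hourly rescoring
the admission window is always available, and a rolling early-stay summary
would leak later information into earlier rows. The four features are
*exactly* collinear (change-since-baseline ≡ current − baseline), so
unpenalized maximum likelihood is unidentifiable; the stage-2 fit is
therefore ridge-stabilized iteratively reweighted least squares with a small
L2 penalty (λ = 1e−4) on the slopes only. This keeps all four named
coefficients finite and reported, leaves fitted probabilities essentially at
their ML values on the identifiable subspace, and handles complete
separation in the same path. The parameter-recovery test accordingly checks
the identifiable contrasts (current + Δbaseline, baseline − Δbaseline,
Δprevious) against 3-standard-error bands at 20,000 windows.

Scoring is causal: a window's risk uses only windows at or before it, so
appending future windows never changes earlier scores — a property the suite
asserts directly. Models serialize to JSON with full-precision coefficients
and a preprocessing version tag; scoring refuses windows normalized under a
different version, and the hourly driver treats such a mismatch as unplanned
downtime rather than scoring under the wrong preprocessing.

Stage-2 training uses the window "ever" label of the four-outcome composite
(whether the encounter deteriorates), matching how the stage-1 scores are
learned; the 48-hour labelling is an evaluation view.

## Risk groups and threshold calibration

`calibrate_thresholds()` grid-searches the unique observed encounter-maximum
scores. Folds are assigned at the *encounter* level (never by window, which
would leak a visit across folds) with a caller-supplied seed. For each
candidate cutoff the held-out visit-level PPV (for the High cutoff) or NPV
(for the Low cutoff) is computed per fold and averaged over folds where it
is defined; the selected cutoff is the one whose cross-validated estimate is
closest to the target (defaults: PPV 40%, NPV 99%), with ties broken toward
the lower cutoff to maximize sensitivity. The two cutoffs are calibrated
independently; if they cross, both collapse to their midpoint with a
warning. Degenerate inputs are explicit: a one-class validation set is an
error, all-identical scores yield the single candidate with a warning, and
an undefined predictive value is reported as absent, never as zero.
Group assignment is `score ≥ thr_high → High`, `score < thr_low → Low`,
otherwise Medium — alerts fire exactly at the threshold, and assignment is
monotone in the score.

The calibration acceptance experiment uses `simulate_calibrated_scores()`:
encounter risks drawn from a Beta distribution with mean 0.10 (shape1 0.35,
giving a dense mass of near-zero risks and a right tail crossing 0.4, as a
ward population has), outcomes drawn Bernoulli from those risks, and score
timelines peaking at exactly the drawn risk. Because the scores are
calibrated by construction, the 40%/99% targets are attainable and the
search should land within sampling noise of them at 2,000 encounters.

## Alerting

`step_alert_engine()` fires a page for a patient if and only if all five
predicates hold: (1) currently High; (2) previous classification not High —
first High, or a return after dropping to Medium/Low; (3) at least 48 h
since the patient's last alert; (4) fewer than 5 alerts so far (the cap is
configurable and can be disabled to reproduce earlier uncapped behaviour);
(5) no ICU-return silence active (each return to the ward silences 24 h).
Rules (2) and (3) are conjunctive — a transition during the 48-h window does
not re-arm it early — the fewest-alerts reading consistent with minimizing
alert fatigue. State is per encounter and resets at discharge, so the 48-h
clock does not survive a readmission. Suppressed High status still appears
in the census and sign-out channels. Alerts fan out to the team phone and
charge-nurse phone with a fixed message template; the twice-daily
charge-nurse census lists the whole ward sorted High→Medium→Low, and the
daily palliative digest lists exactly the patients whose *first-ever* High
of the encounter fell in the trailing 24 h. The engine's correctness is
checked against a brute-force oracle that re-evaluates all five predicates
from raw history on 1,000 random classification streams.

## Monitoring metrics and the hourly driver

AUC is rank-based (Mann–Whitney, ties at ½) and computed at the *window*
level for both the "ever" and "within 48 h" labellings — predictions are
per-window, and no convention fixes an encounter-level aggregation.
Encounter-level PPV of alerted visits reuses the calibration definition
verbatim (one source of truth, enforced by a cross-module test).
Maximum-risk-group sensitivity partitions outcome encounters by the highest
group reached during the stay and always sums to 1. Alert volumes count a
patient/timestamp pair once regardless of channel fan-out and include
zero-alert days. Adherence offers two operationalizations of "vitals
reassessed after an alert": the default counts ≥ 4 distinct assessment times
in the following 24 h; a strict mode requires every gap ≤ 4 h. Strict
adherence implies count adherence, and both are reported as weekly
percentages.

The replay driver iterates an hourly cycle over simulated time. On extract
failure it reuses the cached extract if at most 3 h old (`stale_ok`),
otherwise declares unplanned downtime, notifying on the transition in and
out rather than every cycle; planned outage windows are announced once and
logged without notification spam. The run log covers every hour exactly
once, carries fractional `down_hours` so sub-hour outages are representable,
and feeds `uptime()` directly (percentages reported to one decimal). The
entire replay is a pure function of cohort, scenario and configuration, and
determinism is asserted end to end.

## Problem sizes and runtime choices

The shipped experiments are sized for a laptop-class single core: cohorts of
300–1,000 encounters, stage-1 searches with `max_terms` 7–13 and 10–25
candidate knots per variable, a 2,000-encounter calibration run, and replays
of a few simulated days over a ~25-patient ward. The planted-signal check
fits on two-thirds of a 420-encounter cohort and evaluates held-out
next-48-h AUC (and a label-permuted refit as the chance-level control; the
permuted model is evaluated under the "ever" labelling, where the null has
usable power — permutation leaves so few next-48-h positive windows that its
AUC is noisy at this size). Full defaults (`max_terms = 21`, 100 knots)
remain appropriate for larger cohorts.

## Known limitations

* Stage 1 is least-squares MARS on binary labels; a GLM-MARS variant might
  calibrate better in the tails but is not implemented.
* The synthetic severity process is univariate; real deterioration is
  multi-dimensional, and feature correlations here arise only through the
  shared latent factor.
* Threshold calibration treats the High and Low cutoffs independently; a
  joint search could trade PPV against NPV explicitly.
* Categorical observations (e.g. oxygen delivery device) are not windowed;
  only numeric features are handled.
* The replay rescans each ward patient's full stay every hour. This is
  idempotent and matches an hourly batch design, but is not an incremental
  scorer.
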