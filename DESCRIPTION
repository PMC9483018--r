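Package: chartward
Title: Early-Warning Pipeline for Clinical Deterioration on a General
    Internal Medicine Ward
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation, modelling and deployment-replay toolkit for an
    inpatient early-warning system. Generates seeded synthetic general
    internal medicine (GIM) cohorts with irregular vitals and labs,
    competing deterioration outcomes and data-entry artifacts; builds
    6-hour windowed, percentile-trimmed, normalized and imputed feature
    matrices; fits a two-stage time-aware multivariate adaptive
    regression spline (MARS) risk model (forward hinge-basis growth with
    GCV backward pruning, followed by a logistic model over score-timeline
    features); calibrates High/Medium/Low risk-group thresholds against
    positive and negative predictive value targets by encounter-level
    cross-validation; replays an hourly scoring loop with an
    alert-fatigue suppression state machine, stale-extract fallback and
    downtime bookkeeping; and computes the deployment monitoring metrics
    (AUC, encounter-level PPV, maximum-risk-group sensitivity, alert
    volumes, pathway adherence, uptime).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
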