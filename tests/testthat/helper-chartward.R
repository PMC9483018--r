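# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; larger fixtures are built lazily and cached for the
# session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

utc <- function(x) as.POSIXct(x, tz = "UTC")

# hand-built encounters for windowing edge cases
make_encounter <- function(id, admit, los_h, outcome_type = "none",
                           outcome_h = NA, icu_return_h = NA, age = 70,
                           sex = "F") {
  admit <- utc(admit)
  data.frame(
    encounter_id = id,
    admit_ts = admit,
    discharge_ts = admit + los_h * 3600,
    age = age, sex = sex,
    outcome_type = outcome_type,
    outcome_ts = if (is.na(outcome_h)) utc(NA) else admit + outcome_h * 3600,
    icu_return_ts = if (is.na(icu_return_h)) utc(NA) else
      admit + icu_return_h * 3600,
    stringsAsFactors = FALSE
  )
}

make_obs <- function(id, admit, hours, feature, values) {
  data.frame(encounter_id = id, timestamp = utc(admit) + hours * 3600,
             feature = feature, value = values, stringsAsFactors = FALSE)
}

# medium cohort reused across files (simulation is seeded, so sharing is
# safe)
shared_cohort <- function() {
  cached("cohort_500", function() {
    simulate_cohort(sim_config(n_encounters = 500, seed = 4242))
  })
}

# small fitted deployment (cohort + model + params + thresholds) for
# pipeline tests
tiny_deployment <- function() {
  cached("tiny_deployment", function() {
    cfg <- sim_config(n_encounters = 25, seed = 77)
    co <- simulate_cohort(cfg)
    pf <- prepare_features(co$encounters, co$observations)
    model <- fit_time_aware(pf$windows, max_terms = 7, degree = 1,
                            max_knots = 10)
    thr <- structure(list(thr_high = 0.5, thr_low = 0.1,
                          target_ppv = 0.4, target_npv = 0.99,
                          achieved_ppv = NA, achieved_npv = NA,
                          cv_folds = 10L, seed = 1L),
                     class = "risk_thresholds")
    list(cohort = co, params = pf$params, windows = pf$windows,
         model = model, thresholds = thr,
         day0 = utc(format(min(co$encounters$admit_ts), "%Y-%m-%d")))
  })
}

# ---- independent alert-protocol oracle --------------------------------
# Literal re-evaluation of the five predicates from the raw per-patient
# history, written without the engine's state bookkeeping: for each
# classification in time order an alert fires iff (1) High now, (2) not
# High at the previous classification, (3) >= 48 h since this patient's
# previous alert, (4) fewer than 5 alerts so far, (5) no ICU return within
# the past 24 h.
oracle_alert_times <- function(times_h, groups, icu_return_h = numeric(0),
                               suppression_h = 48, icu_silence_h = 24,
                               max_alerts = 5) {
  alerts <- numeric(0)
  prev_group <- "unseen"
  for (i in seq_along(times_h)) {
    t <- times_h[i]
    g <- groups[i]
    silenced <- any(icu_return_h <= t & t < icu_return_h + icu_silence_h)
    fire <- g == "High" &&
      prev_group != "High" &&
      (length(alerts) == 0 || t >= alerts[length(alerts)] + suppression_h) &&
      length(alerts) < max_alerts &&
      !silenced
    if (fire) alerts <- c(alerts, t)
    prev_group <- g
  }
  alerts
}

# random classification stream for one patient
random_stream <- function(n_steps = 120) {
  groups <- character(n_steps)
  g <- sample(c("Low", "Medium", "High"), 1)
  for (i in seq_len(n_steps)) {
    if (runif(1) < 0.25) g <- sample(c("Low", "Medium", "High"), 1)
    groups[i] <- g
  }
  icu <- if (runif(1) < 0.3) sort(sample(0:(n_steps - 1), sample(1:2, 1)))
  else numeric(0)
  list(times_h = 0:(n_steps - 1), groups = groups, icu_return_h = icu)
}

# run the production engine over one patient's stream
engine_alert_times <- function(stream, t0 = utc("2024-01-01"),
                               config = alert_config()) {
  state <- new_alert_state()
  fired <- numeric(0)
  for (i in seq_along(stream$times_h)) {
    t <- t0 + stream$times_h[i] * 3600
    returns <- if (stream$times_h[i] %in% stream$icu_return_h) "p1"
    else character(0)
    step <- step_alert_engine(
      state,
      data.frame(patient_id = "p1", group = stream$groups[i],
                 stringsAsFactors = FALSE),
      returns, t, config)
    state <- step$state
    if (nrow(step$events)) fired <- c(fired, stream$times_h[i])
  }
  fired
}
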