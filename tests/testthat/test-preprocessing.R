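test_that("exclusion criteria apply to training data only, with inclusive boundaries", {
  enc <- rbind(
    make_encounter("short", "2024-01-01", 6),
    make_encounter("exact8", "2024-01-01", 8),
    make_encounter("normal", "2024-01-01", 100),
    make_encounter("exact40d", "2024-01-01", 40 * 24),
    make_encounter("long", "2024-01-01", 41 * 24)
  )
  kept <- apply_exclusions(enc, "train")
  expect_setequal(kept$encounter_id, c("exact8", "normal", "exact40d"))
  expect_identical(apply_exclusions(enc, "deploy"), enc)
})

test_that("windowing covers the effective stay in 6-h intervals with correct aggregates", {
  enc <- make_encounter("e1", "2024-03-01", 13)
  obs <- make_obs("e1", "2024-03-01", c(1, 5), "heart_rate", c(80, 90))
  w <- build_windows(enc, obs)
  expect_equal(nrow(w), 3)          # ceil(13 / 6), final window partial
  expect_equal(w$window_index, 0:2)
  expect_equal(w$heart_rate, c(85, NA, NA))              # duplicates averaged
  expect_equal(w$heart_rate_measured, c(1L, 0L, 0L))
  # staleness clock: 0 when measured; window 1 ends at h12, last obs h5
  expect_equal(w$heart_rate_time_since_measured, c(0, 7, 8))
  # final partial window ends at the stay end
  expect_equal(as.numeric(w$window_end[3] - w$window_start[3], units = "hours"), 1)

  # windows stop at the outcome, not discharge
  enc2 <- make_encounter("e2", "2024-03-01", 48, outcome_type = "icu",
                         outcome_h = 20)
  w2 <- build_windows(enc2, make_obs("e2", "2024-03-01", 2, "heart_rate", 80))
  expect_equal(nrow(w2), 4)         # ceil(20 / 6)

  # observations outside the stay are dropped with a warning
  bad <- rbind(obs, make_obs("e1", "2024-03-01", 20, "heart_rate", 99))
  expect_warning(w3 <- build_windows(enc, bad), "outside")
  expect_equal(w3$heart_rate, w$heart_rate)

  # never-measured feature: clock counts from admission
  wj <- build_windows(enc, obs, features = c("heart_rate", "glucose"))
  expect_equal(wj$glucose_measured, c(0L, 0L, 0L))
  expect_equal(wj$glucose_time_since_measured, c(6, 12, 13))
})

test_that("window labels are consistent with the outcome", {
  enc <- make_encounter("e1", "2024-03-01", 80, outcome_type = "death",
                        outcome_h = 80)
  w <- build_windows(enc, make_obs("e1", "2024-03-01", 1, "hr", 80))
  expect_true(all(w$outcome_ever == 1L))
  expect_true(all(w$outcome_within_48h <= w$outcome_ever))
  expect_equal(w$outcome_within_48h[nrow(w)], 1L)
  # early windows (> 48 h before the outcome) are not labelled imminent
  expect_equal(w$outcome_within_48h[1], 0L)

  w0 <- build_windows(make_encounter("e2", "2024-03-01", 80),
                      make_obs("e2", "2024-03-01", 1, "hr", 80))
  expect_true(all(w0$outcome_ever == 0L))
  expect_true(all(w0$outcome_within_48h == 0L))
})

test_that("normalization uses linear-interpolation training percentiles", {
  enc <- make_encounter("e1", "2024-03-01", 600)
  obs <- make_obs("e1", "2024-03-01", 6 * (0:99) + 1, "f",
                  as.numeric(1:100))   # one observation per window
  w <- build_windows(enc, obs)
  p <- fit_normalization(w)
  expect_equal(p$q01, 1.99)     # 1 + 0.01 * 99
  expect_equal(p$q99, 99.01)    # 1 + 0.99 * 99
  expect_false(p$degenerate)

  const <- make_obs("e1", "2024-03-01", c(1, 7), "f", c(5, 5))
  wc <- build_windows(enc, const)
  expect_warning(pc <- fit_normalization(wc), "constant")
  expect_true(pc$degenerate)
  expect_equal(normalize_feature(c(4, 5, 6), pc, "f"), c(0.5, 0.5, 0.5))
})

test_that("normalization clips artifacts to the unit interval", {
  p <- structure(
    data.frame(feature = "temperature", q01 = 34.8, q99 = 38.3,
               train_mean_normalized = 0.5, degenerate = FALSE,
               stringsAsFactors = FALSE),
    version = "v1", class = c("normalization_params", "data.frame"))
  expect_identical(normalize_feature(700, p, "temperature"), 1)
  expect_identical(normalize_feature(6932, p, "temperature"), 1)
  expect_identical(normalize_feature(34.8, p, "temperature"), 0)
  expect_equal(normalize_feature(36.55, p, "temperature"), 0.5)
  expect_error(normalize_feature(1, p, "unknown"), "unknown",
               class = "chartward_config_error")
})

test_that("imputation is LOCF then training mean, idempotent, and complete", {
  p <- structure(
    data.frame(feature = "f", q01 = 0, q99 = 1,
               train_mean_normalized = 0.3, degenerate = FALSE,
               stringsAsFactors = FALSE),
    version = "v1", class = c("normalization_params", "data.frame"))
  w <- data.frame(encounter_id = "e1", window_index = 0:2,
                  f = c(NA, 0.4, NA), f_measured = c(0L, 1L, 0L),
                  f_time_since_measured = c(6, 0, 6))
  attr(w, "features") <- "f"
  out <- impute_windows(w, p)
  expect_equal(out$f, c(0.3, 0.4, 0.4))
  expect_identical(impute_windows(out, p)$f, out$f)    # idempotent
  expect_equal(out$f_measured, w$f_measured)           # flags untouched

  w2 <- w; w2$f <- c(0.1, 0.2, 0.9)
  attr(w2, "features") <- "f"
  expect_equal(impute_windows(w2, p)$f, w2$f)          # fully observed

  w3 <- w; w3$f <- c(NA_real_, NA_real_, NA_real_)
  attr(w3, "features") <- "f"
  expect_equal(impute_windows(w3, p)$f, rep(0.3, 3))   # fully missing
})

test_that("the processed feature matrix is complete and bounded even under heavy corruption", {
  co <- simulate_cohort(sim_config(n_encounters = 20, seed = 55,
                                   artifact_rate = 1))
  pf <- prepare_features(co$encounters, co$observations)
  feats <- attr(pf$windows, "features")
  vals <- as.matrix(pf$windows[, feats])
  expect_false(anyNA(vals))
  expect_true(min(vals) >= 0 && max(vals) <= 1)

  # window count invariant over a clean simulated cohort
  co2 <- simulate_cohort(sim_config(n_encounters = 30, seed = 56))
  w <- build_windows(co2$encounters, co2$observations)
  cnt <- table(w$encounter_id)
  enc <- co2$encounters
  end <- ifelse(is.na(enc$outcome_ts), enc$discharge_ts, pmin(enc$discharge_ts, enc$outcome_ts))
  stay_h <- (as.numeric(end) - as.numeric(enc$admit_ts)) / 3600
  expect_equal(as.integer(cnt[enc$encounter_id]), as.integer(ceiling(stay_h / 6)),
               ignore_attr = TRUE)
})

test_that("normalization refit on simulated vitals lands near clinical percentiles", {
  co <- shared_cohort()
  pf <- prepare_features(co$encounters, co$observations)
  temp <- pf$params[pf$params$feature == "temperature", ]
  expect_lt(abs(temp$q01 - 34.8), 1.2)
  expect_lt(abs(temp$q99 - 38.3), 1.2)
})

test_that("assay conversion is piecewise by effective-from timestamp", {
  obs <- make_obs("e1", "2024-03-01", c(1, 10, 30), "troponin", c(0.1, 0.2, 0.3))
  expect_identical(convert_assay(obs, NULL), obs)

  m <- assay_map("troponin", utc("2024-03-01") + 5 * 3600, scale = 1000)
  out <- convert_assay(obs, m)
  expect_equal(out$value, c(0.1, 200, 300))

  m2 <- assay_map(c("troponin", "troponin"),
                  utc("2024-03-01") + c(5, 20) * 3600,
                  scale = c(1000, 1), offset = c(0, 7))
  out2 <- convert_assay(obs, m2)
  expect_equal(out2$value, c(0.1, 200, 0.3 + 7))   # latest entry wins

  expect_warning(convert_assay(obs, assay_map("bnp", "2024-03-01")),
                 "not present")
})
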