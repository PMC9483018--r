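test_that("cohort simulation is a deterministic function of config and seed", {
  cfg <- sim_config(n_encounters = 40, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c2 <- simulate_cohort(sim_config(n_encounters = 40, seed = 10))
  expect_false(identical(a$observations$value, c2$observations$value))

  # observations lie within the stay; outcomes lie in (admit, discharge]
  enc <- a$encounters
  m <- match(a$observations$encounter_id, enc$encounter_id)
  expect_true(all(a$observations$timestamp >= enc$admit_ts[m]))
  expect_true(all(a$observations$timestamp <= enc$discharge_ts[m]))
  has_out <- enc$outcome_type != "none"
  expect_true(all(!is.na(enc$outcome_ts[has_out])))
  expect_true(all(is.na(enc$outcome_ts[!has_out])))
  expect_true(all(enc$outcome_ts[has_out] > enc$admit_ts[has_out]))
  expect_true(all(enc$outcome_ts[has_out] <= enc$discharge_ts[has_out]))
})

test_that("outcome mix controls the empirical outcome distribution", {
  all_none <- simulate_cohort(sim_config(
    n_encounters = 60, seed = 2,
    outcome_mix = c(none = 1, death = 0, icu = 0, stepup = 0, palliative = 0)))
  expect_true(all(is.na(all_none$encounters$outcome_ts)))
  expect_true(all(all_none$encounters$outcome_type == "none"))

  # default mix at n = 500: each fraction within 3 binomial SDs
  co <- shared_cohort()
  mix <- c(none = 0.88, death = 0.04, icu = 0.05, stepup = 0.02,
           palliative = 0.01)
  n <- nrow(co$encounters)
  obs_frac <- table(factor(co$encounters$outcome_type, levels = names(mix))) / n
  for (k in names(mix)) {
    sd_k <- sqrt(mix[k] * (1 - mix[k]) / n)
    expect_lt(abs(obs_frac[k] - mix[k]), 3 * sd_k + 1e-12)
  }
})

test_that("artifact injection corrupts the requested seeded fraction and nothing else", {
  co <- simulate_cohort(sim_config(n_encounters = 10, seed = 31,
                                   artifact_rate = 0))
  expect_identical(inject_artifacts(co$observations, 0, seed = 5),
                   co$observations)
  expect_error(inject_artifacts(co$observations, 1.5), "artifact_rate")

  cat <- default_feature_catalog()
  ten <- co$observations[1:10, ]
  dirty <- inject_artifacts(ten, 1, seed = 8)
  m <- match(dirty$feature, cat$feature)
  expect_true(all(dirty$value < cat$plausible_low[m] |
                    dirty$value > cat$plausible_high[m]))

  big <- co$observations[rep(seq_len(nrow(co$observations)),
                             length.out = 10000), ]
  d2 <- inject_artifacts(big, 0.01, seed = 13)
  n_corrupt <- sum(d2$value != big$value)
  expect_lt(abs(n_corrupt - 100), 3 * sqrt(10000 * 0.01 * 0.99))
  # determinism of the corruption draw
  d3 <- inject_artifacts(big, 0.01, seed = 13)
  expect_identical(d2, d3)
})

test_that("cohort CSV round trip is the identity and schema errors are reported", {
  co <- shared_cohort()
  d <- withr::local_tempdir()
  write_cohort(co$encounters, co$observations, d)
  back <- read_cohort(d)
  expect_equal(nrow(back$encounters), nrow(co$encounters))
  expect_equal(nrow(back$observations), nrow(co$observations))
  expect_identical(back$encounters$encounter_id, co$encounters$encounter_id)
  expect_identical(back$encounters$outcome_type, co$encounters$outcome_type)
  # timestamps serialized at second precision; values at full precision
  expect_true(all(abs(as.numeric(back$encounters$admit_ts) -
                        as.numeric(co$encounters$admit_ts)) < 1))
  expect_equal(back$observations$value, co$observations$value)
  expect_identical(is.na(back$encounters$outcome_ts),
                   is.na(co$encounters$outcome_ts))

  # missing required column is a parse error naming the column
  obs2 <- co$observations
  names(obs2)[names(obs2) == "timestamp"] <- "ts"
  d2 <- withr::local_tempdir()
  write.csv(obs2, file.path(d2, "observations.csv"), row.names = FALSE)
  enc_out <- co$encounters
  for (col in c("admit_ts", "discharge_ts", "outcome_ts", "icu_return_ts"))
    enc_out[[col]] <- format(enc_out[[col]], "%Y-%m-%dT%H:%M:%SZ")
  write.csv(enc_out, file.path(d2, "encounters.csv"), row.names = FALSE)
  expect_error(read_cohort(d2), "timestamp", class = "chartward_parse_error")
})

test_that("default configuration yields a realistic ward census with recoverable signal", {
  co <- cached("census_cohort", function() {
    simulate_cohort(sim_config(n_encounters = 990, seed = 606))
  })
  enc <- co$encounters
  # daily census over a 90-day window after warm-up, vs the Little's-law
  # prediction admission_rate x mean LOS
  days <- seq(min(enc$admit_ts) + 10 * 86400, by = "day", length.out = 90)
  census <- vapply(days, function(d) {
    sum(enc$admit_ts <= d & enc$discharge_ts > d)
  }, numeric(1))
  expect_gt(mean(census), 70)
  expect_lt(mean(census), 100)
  little <- 11 * exp(log(183) - 0.8^2 / 2 + 0.8^2 / 2) / 24
  expect_lt(abs(mean(census) - little) / little, 0.2)

  # a plain logistic model on last-observed severity-loaded features must
  # find signal (the generator does not produce pure noise)
  pf <- prepare_features(enc, co$observations)
  w <- pf$windows
  dt <- data.table::as.data.table(w)
  last <- dt[, .SD[which.max(window_index)], by = encounter_id]
  set.seed(1)
  test_ids <- sample(enc$encounter_id, 300)
  tr <- !last$encounter_id %in% test_ids
  fit <- glm(outcome_ever ~ respirations + systolic_bp + troponin + temperature,
             binomial, data = last[tr])
  p <- predict(fit, newdata = last[!tr], type = "response")
  expect_gt(compute_auc(p, last$outcome_ever[!tr]), 0.65)
})
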