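# minimal window table for hand-built models: one feature "f"
toy_windows <- function(enc_id, values, version = "v1") {
  w <- data.frame(
    encounter_id = enc_id,
    window_index = unlist(lapply(table(enc_id)[unique(enc_id)], seq_len)) - 1L,
    f = values, f_measured = 1L, f_time_since_measured = 0,
    age = 70, sex_female = 1L,
    outcome_ever = 0L, outcome_within_48h = 0L,
    stringsAsFactors = FALSE
  )
  attr(w, "features") <- "f"
  attr(w, "norm_version") <- version
  w
}

toy_model <- function(stage2_coef = c(0, 2, 0.5, 1, 0.5), version = "v1") {
  stage1 <- structure(list(
    terms = list(list(), list(list(var = 1L, knot = 0.2, sign = 1))),
    coefficients = c(0.1, 1), gcv = 0, gcv_forward = 0, n = 100,
    features = c("f", "f_measured", "f_time_since_measured", "age",
                 "sex_female"),
    degree = 1, gcv_penalty = 3), class = "mars_model")
  structure(list(
    stage1 = stage1,
    stage2 = list(coefficients = setNames(
      stage2_coef, c("(Intercept)", "current_score", "baseline_score",
                     "delta_prev", "delta_baseline")), lambda = 1e-4),
    preprocessing_version = version,
    feature_columns = c("f", "f_measured", "f_time_since_measured", "age",
                        "sex_female"),
    label = "outcome_ever"), class = "time_aware_model")
}

test_that("score-timeline features follow their definitions", {
  tf <- derive_time_features(c(0.1, 0.3, 0.2))
  expect_equal(tf$current_score, c(0.1, 0.3, 0.2))
  expect_equal(tf$baseline_score, rep(0.1, 3))
  expect_equal(tf$delta_prev, c(0, 0.2, -0.1))
  expect_equal(tf$delta_baseline, c(0, 0.2, 0.1))
  expect_equal(tf$delta_baseline, tf$current_score - tf$baseline_score)

  one <- derive_time_features(0.4)
  expect_equal(unlist(one), c(current_score = 0.4, baseline_score = 0.4,
                              delta_prev = 0, delta_baseline = 0))
  const <- derive_time_features(rep(0.2, 5))
  expect_true(all(const$delta_prev == 0) && all(const$delta_baseline == 0))
  expect_error(derive_time_features(numeric(0)), "empty")
})

test_that("fitting is deterministic and statistically sane", {
  co <- simulate_cohort(sim_config(n_encounters = 60, seed = 19))
  pf <- prepare_features(co$encounters, co$observations)
  m1 <- fit_time_aware(pf$windows, max_terms = 7, degree = 1, max_knots = 10)
  m2 <- fit_time_aware(pf$windows, max_terms = 7, degree = 1, max_knots = 10)
  expect_identical(m1$stage2$coefficients, m2$stage2$coefficients)
  expect_identical(m1$stage1$coefficients, m2$stage1$coefficients)
  expect_length(m1$stage2$coefficients, 5L)   # intercept + 4 slopes
  # fitted stage 2 explains at least as much as the intercept-only model
  expect_gte(m1$stage2$loglik, m1$stage2$loglik_null)

  r <- predict_risk(m1, pf$windows)
  expect_true(all(r$score > 0 & r$score < 1))
  expect_equal(nrow(r), nrow(pf$windows))
})

test_that("risk scores are causal in the window sequence", {
  m <- toy_model()
  full <- toy_windows(rep("e1", 6), c(0.1, 0.5, 0.3, 0.9, 0.2, 0.7))
  head3 <- full[1:3, ]; attr(head3, "features") <- "f"
  attr(head3, "norm_version") <- "v1"
  r_full <- predict_risk(m, full)
  r_head <- predict_risk(m, head3)
  expect_equal(r_full$score[1:3], r_head$score, tolerance = 1e-14)
})

test_that("positive stage-2 weights make a rising stage-1 timeline monotone in risk", {
  m <- toy_model(stage2_coef = c(-1, 2, 0.5, 1, 0.5))
  w <- toy_windows(rep("e1", 5), c(0.25, 0.35, 0.5, 0.7, 0.9))
  r <- predict_risk(m, w)
  expect_true(all(diff(r$score) > 0))
})

test_that("stage-2 coefficients are recovered on synthetic timelines at n = 20,000", {
  set.seed(1234)
  n_enc <- 4000; k <- 5                      # 20,000 windows
  stage1 <- toy_model()$stage1
  # true coefficients on the identifiable contrasts:
  #   eta = b0 + (b1+b4) * current + (b2-b4) * baseline + b3 * delta_prev
  b <- c(-2, 3, 1, 2, 1.5)
  f <- runif(n_enc * k)
  w <- toy_windows(rep(sprintf("s%04d", seq_len(n_enc)), each = k), f)
  s1 <- 0.1 + pmax(0, f - 0.2)
  tf <- do.call(rbind, lapply(split(s1, w$encounter_id), derive_time_features))
  eta <- b[1] + as.matrix(tf) %*% b[-1]
  w$outcome_ever <- rbinom(length(eta), 1, plogis(eta))
  fit <- fit_time_aware(w, stage1 = stage1)
  bh <- fit$stage2$coefficients
  V <- fit$stage2$vcov
  contrasts <- list(
    current = c(0, 1, 0, 0, 1),    # b1 + b4
    baseline = c(0, 0, 1, 0, -1),  # b2 - b4
    dprev = c(0, 0, 0, 1, 0),
    icept = c(1, 0, 0, 0, 0)
  )
  truth <- c(b[2] + b[5], b[3] - b[5], b[4], b[1])
  for (i in seq_along(contrasts)) {
    cvec <- contrasts[[i]]
    est <- sum(cvec * bh)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    expect_lt(abs(est - truth[i]), 3 * se + 1e-8)
  }
})

test_that("model persistence round-trips predictions and guards versions", {
  co <- simulate_cohort(sim_config(n_encounters = 40, seed = 23))
  pf <- prepare_features(co$encounters, co$observations, version = "v7")
  m <- fit_time_aware(pf$windows, max_terms = 7, degree = 2, max_knots = 10)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  r1 <- predict_risk(m, pf$windows)
  r2 <- predict_risk(m2, pf$windows)
  expect_lt(max(abs(r1$score - r2$score)), 1e-12)

  expect_error(load_model(path, expected_version = "v8"), "v7",
               class = "chartward_version_error")

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", bad)
  expect_error(load_model(bad), class = "chartward_parse_error")

  # scoring windows preprocessed under another version is refused
  w_other <- pf$windows
  attr(w_other, "norm_version") <- "v8"
  expect_error(predict_risk(m, w_other), class = "chartward_version_error")
})
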