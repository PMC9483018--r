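test_that("rank-based AUC matches pair counting, with ties at half weight", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)

  # hand-countable fixture: scores (.9,.7,.5,.5,.3,.1), labels (1,0,1,0,0,1)
  # pairs: 3 pos x 3 neg = 9; concordant 5.5 of 9 (one tie)
  s <- c(0.9, 0.7, 0.5, 0.5, 0.3, 0.1)
  y <- c(1, 0, 1, 0, 0, 1)
  manual <- 0
  for (i in which(y == 1)) for (j in which(y == 0)) {
    manual <- manual + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  }
  expect_equal(compute_auc(s, y), manual / 9)

  # independent labels: AUC near 1/2 at n = 10,000
  set.seed(77)
  expect_lt(abs(compute_auc(runif(10000), rbinom(10000, 1, 0.3)) - 0.5), 0.02)

  expect_warning(a <- compute_auc(1:5, rep(1, 5)), "one outcome class")
  expect_true(is.na(a))

  # agreement with an established implementation on random data
  set.seed(78)
  s2 <- runif(500); y2 <- rbinom(500, 1, 0.2)
  expect_equal(compute_auc(s2, y2),
               as.numeric(pROC::auc(pROC::roc(y2, s2, quiet = TRUE,
                                              direction = "<"))))

  # mode selects the window labelling from a window table
  w <- data.frame(outcome_ever = c(1, 1, 0, 0),
                  outcome_within_48h = c(1, 0, 0, 0))
  expect_equal(compute_auc(c(4, 3, 2, 1), w, "ever"), 1)
  expect_equal(compute_auc(c(4, 3, 2, 1), w, "next_48h"), 1)
})

test_that("maximum-risk-group sensitivity partitions outcome encounters", {
  g <- data.frame(
    encounter_id = rep(sprintf("e%02d", 1:12), each = 2),
    group = c(rbind(rep("Low", 12),
                    c(rep("High", 5), rep("Medium", 4), "Low",
                      "High", "Medium"))),
    stringsAsFactors = FALSE)
  oc <- data.frame(encounter_id = sprintf("e%02d", 1:12),
                   outcome = c(rep(1, 10), 0, 0))
  sens <- sensitivity_by_max_group(g, oc)
  expect_equal(unname(sens), c(0.5, 0.4, 0.1))
  expect_equal(sum(sens), 1)
  expect_equal(pooled_sensitivity(sens), 0.9)

  all_high <- data.frame(encounter_id = c("a", "b"), group = "High")
  oc2 <- data.frame(encounter_id = c("a", "b"), outcome = c(1, 1))
  expect_equal(unname(sensitivity_by_max_group(all_high, oc2)), c(1, 0, 0))
  expect_error(sensitivity_by_max_group(all_high,
                                        data.frame(encounter_id = c("a", "b"),
                                                   outcome = c(0, 0))),
               "no outcome", class = "chartward_config_error")

  # partition property on random inputs
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    gg <- data.frame(encounter_id = rep(seq_len(n), each = 3),
                     group = sample(c("Low", "Medium", "High"), 3 * n, TRUE))
    oo <- data.frame(encounter_id = seq_len(n),
                     outcome = rbinom(n, 1, 0.5))
    if (sum(oo$outcome) == 0) oo$outcome[1] <- 1
    expect_equal(sum(sensitivity_by_max_group(gg, oo)), 1)
  }
})

test_that("alert-volume statistics include zero-alert days", {
  t0 <- utc("2024-02-01 10:00")
  log <- data.frame(
    patient_id = c("a", "b", rep("c", 4)),
    timestamp = c(t0, t0 + 3600, t0 + 2 * 86400 + (1:4) * 3600))
  st <- alert_stats(log, "2024-02-01", "2024-02-03")
  expect_equal(st$daily$count, c(2, 0, 4))
  expect_equal(st$mean, 2)
  expect_equal(st$zero_days, 1)
  expect_equal(st$sd, sd(c(2, 0, 4)))

  st0 <- alert_stats(log[0, ], "2024-02-01", "2024-02-05")
  expect_equal(st0$mean, 0)
  expect_equal(st0$zero_days, 5)

  st1 <- alert_stats(log[1, , drop = FALSE], "2024-02-01", "2024-02-01")
  expect_true(is.na(st1$sd))

  # channel fan-out is not double-counted
  log2 <- log[rep(1:nrow(log), each = 2), ]
  expect_equal(alert_stats(log2, "2024-02-01", "2024-02-03")$daily$count,
               c(2, 0, 4))
})

test_that("pathway adherence counts post-alert vital reassessment", {
  t0 <- utc("2024-03-04 09:00")   # a Monday
  alerts <- data.frame(patient_id = c("a", "b"), timestamp = c(t0, t0 + 3600))
  vit <- function(id, hrs) data.frame(patient_id = id,
                                      timestamp = t0 + hrs * 3600)
  vitals <- rbind(vit("a", c(2, 5, 9, 13, 17, 21)),  # 6 in 24 h -> adherent
                  vit("b", c(3, 9, 15)))             # 3 in 24 h -> not
  wk <- adherence_weekly(alerts, vitals)
  expect_equal(wk$n_alerts, 2)
  expect_equal(wk$n_adherent, 1)
  expect_equal(wk$adherence_pct, 50)

  # 3 adherent of 4 alerts in a week -> 75%
  alerts4 <- data.frame(patient_id = c("a", "b", "c", "d"),
                        timestamp = t0 + (0:3) * 7200)
  v4 <- rbind(vit("a", c(1, 5, 9, 13)), vit("b", c(3, 7, 11, 15)),
              vit("c", c(5, 9, 13, 17)), vit("d", 5))
  expect_equal(adherence_weekly(alerts4, v4)$adherence_pct, 75)

  # strict mode (every-4-h) is never more lenient than count mode
  set.seed(41)
  for (i in 1:20) {
    al <- data.frame(patient_id = "p", timestamp = t0)
    vv <- data.frame(patient_id = "p",
                     timestamp = t0 + sort(runif(sample(1:8, 1), 0, 24)) * 3600)
    cnt <- adherence_weekly(al, vv, mode = "count")$n_adherent
    strict <- adherence_weekly(al, vv, mode = "strict")$n_adherent
    expect_lte(strict, cnt)
  }
})

test_that("uptime reproduces printed downtime arithmetic", {
  t0 <- utc("2024-01-01")
  mk_log <- function(n, planned_h, unplanned_h) {
    status <- rep("ok", n)
    dh <- rep(0, n)
    np <- ceiling(planned_h); nu <- ceiling(unplanned_h)
    status[seq_len(np)] <- "down_planned"
    dh[seq_len(np)] <- c(rep(1, floor(planned_h)),
                         if (planned_h %% 1 > 0) planned_h %% 1)
    idx <- np + seq_len(nu)
    status[idx] <- "down_unplanned"
    dh[idx] <- c(rep(1, floor(unplanned_h)),
                 if (unplanned_h %% 1 > 0) unplanned_h %% 1)
    data.frame(cycle_ts = t0 + 3600 * (0:(n - 1)), status = status,
               down_hours = dh)
  }
  u <- uptime(mk_log(14016, 20, 32.5))
  expect_identical(u$uptime_pct, 99.6)
  expect_identical(u$planned_share_pct, 38.1)
  expect_identical(u$unplanned_share_pct, 61.9)
  expect_equal(u$down_hours, 52.5)

  clean <- data.frame(cycle_ts = t0 + 3600 * (0:99), status = "ok")
  u2 <- uptime(clean)
  expect_equal(u2$uptime_pct, 100)
  expect_true(is.na(u2$planned_share_pct))

  gap <- clean[-5, ]
  expect_error(uptime(gap), "gap", class = "chartward_config_error")
})
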