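# Deployment monitoring metrics: discrimination, encounter-level predictive
# values, maximum-risk-group sensitivity, alert volumes, pathway adherence
# and uptime.

#' Rank-based AUC over prediction windows
#'
#' Mann-Whitney AUC of per-window scores against a binary window label, with
#' tied scores contributing 1/2. When `labels` is a window table, `mode`
#' selects the labelling: `"ever"` uses `outcome_ever` (did the encounter
#' ever reach the outcome) and `"next_48h"` uses `outcome_within_48h` (is
#' the outcome within 48 h of the window end).
#'
#' @param scores Numeric vector of window scores.
#' @param labels Either a 0/1 vector aligned with `scores`, or a windows
#'   data.frame carrying the label columns.
#' @param mode Label selector when `labels` is a windows table.
#' @return AUC in \[0, 1\], or `NA` with a warning when only one class is
#'   present.
#' @export
#' @examples
#' compute_auc(c(.9, .8, .3, .2), c(1, 1, 0, 0))
compute_auc <- function(scores, labels, mode = c("ever", "next_48h")) {
  if (is.data.frame(labels)) {
    mode <- match.arg(mode)
    col <- if (mode == "ever") "outcome_ever" else "outcome_within_48h"
    labels <- labels[[col]]
  }
  y <- as.integer(labels)
  if (length(y) != length(scores)) cw_config_error("scores/labels length mismatch")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one outcome class present", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores)  # midranks give ties weight 1/2
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Encounter-level PPV of alerted encounters
#'
#' Identical, by construction, to [visit_level_ppv()] evaluated at the
#' deployed high-risk threshold — the calibration definition is the single
#' source of truth.
#'
#' @param timelines Risk timelines (`encounter_id`, `score`).
#' @param outcomes Encounter outcomes (`encounter_id`, 0/1 `outcome`) under
#'   the reporting composite.
#' @param thresholds A `risk_thresholds` object (or list with `thr_high`).
#' @return PPV in \[0, 1\], `NA` when no encounter alerted.
#' @export
ppv_alerted_encounters <- function(timelines, outcomes, thresholds) {
  visit_level_ppv(timelines, outcomes, thresholds$thr_high)
}

#' Sensitivity by maximum risk group
#'
#' Among outcome encounters only: the fraction whose maximum risk group over
#' the whole stay was High, Medium, or Low. The three fractions always
#' partition the outcome encounters (they sum to 1). A good deployment keeps
#' the Low fraction near zero.
#'
#' @param groups data.frame `encounter_id`, `group` (one row per window, or
#'   per encounter).
#' @param outcomes data.frame `encounter_id`, 0/1 `outcome`; at least one
#'   outcome encounter required.
#' @return Named numeric `c(High=, Medium=, Low=)`.
#' @export
#' @examples
#' g <- data.frame(encounter_id = c("a", "a", "b"),
#'                 group = c("Medium", "High", "Low"))
#' oc <- data.frame(encounter_id = c("a", "b"), outcome = c(1, 1))
#' sensitivity_by_max_group(g, oc)
sensitivity_by_max_group <- function(groups, outcomes) {
  dt <- as.data.table(groups)
  dt[, grp_ord := factor(as.character(group), levels = RISK_LEVELS,
                         ordered = TRUE)]
  mx <- dt[, .(max_group = as.character(max(grp_ord))), by = encounter_id]
  m <- match(mx$encounter_id, outcomes$encounter_id)
  if (anyNA(m)) {
    cw_config_error("missing outcome label for encounter '%s'",
                    mx$encounter_id[is.na(m)][1])
  }
  y <- as.integer(outcomes$outcome[m])
  if (sum(y == 1L) == 0L) cw_config_error("no outcome encounters present")
  out_groups <- mx$max_group[y == 1L]
  counts <- table(factor(out_groups, levels = c("High", "Medium", "Low")))
  stats::setNames(as.numeric(counts) / sum(counts),
                  c("High", "Medium", "Low"))
}

#' Pool sensitivities across risk groups
#'
#' Sum of the maximum-risk-group sensitivities of the selected groups —
#' e.g. pooling High and Medium gives the fraction of outcome encounters
#' flagged at least Medium at some point.
#'
#' @param sensitivity Named vector as returned by
#'   [sensitivity_by_max_group()].
#' @param groups Groups to pool (default High + Medium).
#' @return A single number in \[0, 1\].
#' @export
pooled_sensitivity <- function(sensitivity, groups = c("High", "Medium")) {
  sum(sensitivity[groups])
}

#' Daily alert-volume statistics
#'
#' Counts unique alerts (a patient/timestamp pair; channel fan-out is not
#' double-counted) per calendar day over the full date range, including
#' zero-alert days, and reports mean, sample SD, median, quartiles and the
#' number of zero-alert days.
#'
#' @param alert_log Alert log (`patient_id`, `timestamp`, possibly one row
#'   per channel).
#' @param start_date,end_date Date range (inclusive, coercible to Date).
#' @return List: `daily` (data.frame date/count), `mean`, `sd`, `median`,
#'   `q25`, `q75`, `zero_days`, `n_days`. `sd` is `NA` for a single day.
#' @export
alert_stats <- function(alert_log, start_date, end_date) {
  days <- seq(as.Date(start_date), as.Date(end_date), by = "day")
  if (length(days) < 1L) cw_config_error("empty date range")
  if (nrow(alert_log)) {
    uni <- unique(data.frame(patient_id = alert_log$patient_id,
                             timestamp = alert_log$timestamp))
    tab <- table(factor(as.character(as.Date(uni$timestamp, tz = "UTC")),
                        levels = as.character(days)))
    counts <- as.integer(tab)
  } else {
    counts <- rep(0L, length(days))
  }
  q <- stats::quantile(counts, c(0.25, 0.5, 0.75), names = FALSE)
  list(
    daily = data.frame(date = days, count = counts),
    mean = mean(counts),
    sd = if (length(counts) > 1L) stats::sd(counts) else NA_real_,
    median = q[2], q25 = q[1], q75 = q[3],
    zero_days = sum(counts == 0L),
    n_days = length(days)
  )
}

#' Weekly adherence to the post-alert clinical pathway
#'
#' The pathway expects frequent vital-sign reassessment after an alert. Two
#' operationalizations are provided: `"count"` (default) declares an alert
#' adherent when at least `min_assessments` (4) distinct vital-sign
#' assessment times fall in the 24 h after it; `"strict"` additionally
#' requires every gap — alert to first assessment, between assessments, and
#' last assessment to the 24-h mark — to be at most `max_gap_h` (4) hours,
#' i.e. vitals measured every 4 h. Strict adherence implies count adherence.
#' Reported as the weekly percentage of adherent alerts (ISO week of the
#' alert).
#'
#' @param alert_log Alert log (`patient_id`, `timestamp`).
#' @param vitals data.frame `patient_id`, `timestamp` of vital-sign
#'   assessment times.
#' @param mode `"count"` or `"strict"`.
#' @param min_assessments Count-mode threshold (default 4).
#' @param max_gap_h Strict-mode maximum gap in hours (default 4).
#' @param follow_up_h Post-alert horizon in hours (default 24).
#' @return data.frame `week`, `n_alerts`, `n_adherent`, `adherence_pct`.
#' @export
adherence_weekly <- function(alert_log, vitals, mode = c("count", "strict"),
                             min_assessments = 4L, max_gap_h = 4,
                             follow_up_h = 24) {
  mode <- match.arg(mode)
  alerts <- unique(data.frame(patient_id = alert_log$patient_id,
                              timestamp = as_utc(alert_log$timestamp)))
  if (nrow(alerts) == 0L) {
    return(data.frame(week = character(0), n_alerts = integer(0),
                      n_adherent = integer(0), adherence_pct = numeric(0)))
  }
  vt <- as.data.table(vitals)
  adherent <- vapply(seq_len(nrow(alerts)), function(i) {
    t0 <- alerts$timestamp[i]
    ts <- sort(unique(vt[patient_id == alerts$patient_id[i] &
                           timestamp > t0 &
                           timestamp <= t0 + follow_up_h * 3600, timestamp]))
    if (mode == "count") {
      length(ts) >= min_assessments
    } else {
      if (!length(ts)) return(FALSE)
      gaps <- diff(c(as.numeric(t0), as.numeric(ts),
                     as.numeric(t0) + follow_up_h * 3600)) / 3600
      all(gaps <= max_gap_h)
    }
  }, logical(1))
  wk <- format(alerts$timestamp, "%G-W%V")
  agg <- aggregate(cbind(n_alerts = rep(1L, length(wk)),
                         n_adherent = as.integer(adherent)) ~ week,
                   data = data.frame(week = wk), FUN = sum)
  agg$adherence_pct <- 100 * agg$n_adherent / agg$n_alerts
  agg[order(agg$week), , drop = FALSE]
}

#' Pipeline uptime and downtime shares
#'
#' Summarizes an hourly run log into percentage uptime and the planned /
#' unplanned shares of total downtime, each rounded to one decimal for
#' reporting (the raw fractions are returned too). The log must cover the
#' period hour by hour with no gaps; a `down_hours` column (in \[0, 1\],
#' defaulting to 1 for down cycles) lets a cycle be partially down, so
#' half-hour outages are representable.
#'
#' @param run_log data.frame `cycle_ts` (hourly, consecutive), `status` in
#'   \{up, ok, stale_ok, planned_down, down_planned, unplanned_down,
#'   down_unplanned\}, optional `down_hours`.
#' @return List: `uptime_pct`, `planned_share_pct`, `unplanned_share_pct`
#'   (1-decimal percentages; shares `NA` with zero downtime), `total_hours`,
#'   `down_hours`, `planned_down_hours`, `unplanned_down_hours`.
#' @export
#' @examples
#' log <- data.frame(
#'   cycle_ts = as.POSIXct("2024-01-01", tz = "UTC") + 3600 * (0:99),
#'   status = c(rep("ok", 98), "down_planned", "down_unplanned"))
#' uptime(log)
uptime <- function(run_log) {
  ts <- as_utc(run_log$cycle_ts)
  if (length(ts) == 0L) cw_config_error("empty run log")
  gaps <- diff(as.numeric(ts))
  if (length(gaps) && any(abs(gaps - 3600) > 1)) {
    cw_config_error("run log has a gap or irregular spacing at position %d",
                    which(abs(gaps - 3600) > 1)[1] + 1L)
  }
  status <- as.character(run_log$status)
  planned <- status %in% c("planned_down", "down_planned")
  unplanned <- status %in% c("unplanned_down", "down_unplanned")
  up <- status %in% c("up", "ok", "stale_ok")
  if (!all(planned | unplanned | up)) {
    cw_config_error("unknown status '%s' in run log",
                    status[!(planned | unplanned | up)][1])
  }
  down_hours <- if ("down_hours" %in% names(run_log)) {
    as.numeric(run_log$down_hours)
  } else {
    as.numeric(planned | unplanned)
  }
  if (any(down_hours < 0 | down_hours > 1)) {
    cw_config_error("'down_hours' entries must lie in [0, 1]")
  }
  total <- length(ts)
  planned_h <- sum(down_hours[planned])
  unplanned_h <- sum(down_hours[unplanned])
  down_h <- planned_h + unplanned_h
  list(
    uptime_pct = round(100 * (total - down_h) / total, 1),
    planned_share_pct = if (down_h > 0) round(100 * planned_h / down_h, 1) else NA_real_,
    unplanned_share_pct = if (down_h > 0) round(100 * unplanned_h / down_h, 1) else NA_real_,
    total_hours = total,
    down_hours = down_h,
    planned_down_hours = planned_h,
    unplanned_down_hours = unplanned_h
  )
}
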