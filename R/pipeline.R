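# The hourly batch loop: extract -> preprocess -> score -> classify ->
# alert -> communicate, with stale-extract fallback and downtime
# bookkeeping, replayed over simulated time.

#' Build a data source over a simulated cohort
#'
#' Returns an extract function `f(t)` emulating the hospital-database pull:
#' it yields the ward census at `t` (encounters admitted and not yet
#' discharged or ended by their outcome) and all observations timestamped at
#' or before `t` for those encounters — the pipeline can never see the
#' future. Extract faults can be injected: within any fault window the
#' function raises an extraction error, which [run_cycle()] absorbs via the
#' stale-cache fallback.
#'
#' @param encounters,observations Cohort tables.
#' @param extract_faults Optional data.frame `start`, `end` of extract
#'   outage windows.
#' @return A function of one argument `t`.
#' @export
make_cohort_source <- function(encounters, observations,
                               extract_faults = NULL) {
  enc <- encounters
  enc_end <- effective_end(enc)
  obs <- as.data.table(observations)
  faults <- coerce_interval_df(extract_faults)
  function(t) {
    t <- as_utc(t)
    if (!is.null(faults) && nrow(faults)) {
      hit <- t >= faults$start & t < faults$end
      if (any(hit)) {
        cw_stop("chartward_extract_error",
                "extract failure (injected fault at %s)", format_iso8601(t))
      }
    }
    on_ward <- enc$admit_ts <= t & enc_end > t
    census <- enc[on_ward, , drop = FALSE]
    o <- obs[encounter_id %in% census$encounter_id & timestamp <= t]
    list(ts = t, census = census, observations = as.data.frame(o))
  }
}

coerce_interval_df <- function(x) {
  if (is.null(x)) return(NULL)
  data.frame(start = as_utc(x$start), end = as_utc(x$end))
}

#' Describe a replay fault schedule
#'
#' `planned` and `unplanned` are pipeline outage windows (the whole hourly
#' cycle does not run: scheduled maintenance, server failure); during a
#' planned window a single pre-announced notification is recorded, with no
#' per-cycle notification spam. `extract_faults` are database extract
#' failures: the cycle still runs and falls back to the most recent cached
#' extract when it is at most 3 h old. Pipeline outage windows must not
#' overlap one another.
#'
#' @param planned,unplanned,extract_faults Each `NULL` or a data.frame with
#'   `start`/`end` timestamps. Fractional-hour windows are allowed and
#'   accounted as partial downtime.
#' @return A `replay_scenario` list.
#' @export
replay_scenario <- function(planned = NULL, unplanned = NULL,
                            extract_faults = NULL) {
  planned <- coerce_interval_df(planned)
  unplanned <- coerce_interval_df(unplanned)
  outages <- rbind(
    if (!is.null(planned)) cbind(planned, type = "down_planned"),
    if (!is.null(unplanned)) cbind(unplanned, type = "down_unplanned")
  )
  if (!is.null(outages) && nrow(outages) > 1L) {
    o <- outages[order(outages$start), ]
    if (any(o$end[-nrow(o)] > o$start[-1])) {
      cw_config_error("overlapping pipeline outage windows in scenario")
    }
  }
  structure(list(outages = outages, extract_faults = extract_faults),
            class = "replay_scenario")
}

STALE_EXTRACT_MAX_H <- 3

#' Run one hourly pipeline cycle
#'
#' Attempts a fresh extract from `source`. On success the ward census is
#' preprocessed under the model's normalization parameters, scored with the
#' time-aware model, classified into risk groups, and fed through the alert
#' engine; if the previous cycle was unplanned downtime a recovery
#' notification is emitted. On extract failure the cycle falls back to the
#' cached extract when it is at most 3 h old (`status = "stale_ok"`);
#' otherwise the cycle is unplanned downtime (`status = "down_unplanned"`,
#' `n_scored = 0`) and a downtime notification is emitted on the transition
#' into downtime. A mismatch between the model's preprocessing version and
#' the supplied normalization parameters aborts the cycle as unplanned
#' downtime — scoring under the wrong preprocessing would be silently
#' wrong, which is worse than being down.
#'
#' @param t Cycle time (strictly later than the previous cycle).
#' @param source Extract function from [make_cohort_source()].
#' @param cache Previous successful extract (`list(ts, census,
#'   observations)`) or `NULL`.
#' @param model A `time_aware_model`.
#' @param params The `normalization_params` the deployment runs under.
#' @param thresholds A `risk_thresholds` object.
#' @param alert_state Current [new_alert_state()] state.
#' @param history Classification history data.frame (`patient_id`,
#'   `timestamp`, `group`) accumulated so far.
#' @param config An [alert_config()].
#' @param prev_status Status string of the previous cycle (for notification
#'   edge-triggering).
#' @return List: `result` (one-row data.frame: `cycle_ts`, `status`,
#'   `n_scored`, `n_alerts`, `n_notifications`), `cache`, `alert_state`,
#'   `history`, `alerts`, `comms` (list of payloads), `notifications`
#'   (list), `classifications`.
#' @export
run_cycle <- function(t, source, cache, model, params, thresholds,
                      alert_state, history, config = alert_config(),
                      prev_status = "ok") {
  t <- as_utc(t)
  notifications <- list()
  comms <- list()
  alerts <- empty_alert_log()
  classifications <- data.frame(patient_id = character(0),
                                group = character(0))

  version_ok <- identical(attr(params, "version") %||% "unversioned",
                          model$preprocessing_version)
  extract <- NULL
  status <- "ok"
  if (!version_ok) {
    status <- "down_unplanned"
    notifications <- list(list(kind = "unplanned_downtime_start",
                               timestamp = t,
                               reason = "preprocessing version mismatch"))
  } else {
    extract <- tryCatch(source(t), error = function(e) NULL)
    if (is.null(extract)) {
      if (!is.null(cache) && hours_between(t, cache$ts) <= STALE_EXTRACT_MAX_H) {
        extract <- cache
        status <- "stale_ok"
      } else {
        status <- "down_unplanned"
        if (!identical(prev_status, "down_unplanned")) {
          notifications <- list(list(kind = "unplanned_downtime_start",
                                     timestamp = t,
                                     reason = "data extract unavailable"))
        }
      }
    } else {
      cache <- extract
    }
  }

  n_scored <- 0L
  if (status %in% c("ok", "stale_ok")) {
    if (identical(prev_status, "down_unplanned")) {
      notifications <- c(notifications,
                         list(list(kind = "unplanned_downtime_end",
                                   timestamp = t)))
    }
    census <- extract$census
    if (nrow(census)) {
      # score what is known *now*: stays truncated at the extract time,
      # future outcomes unknown
      enc_now <- census
      enc_now$discharge_ts <- rep(extract$ts, nrow(enc_now))
      enc_now$outcome_type <- "none"
      enc_now$outcome_ts <- as.POSIXct(NA, tz = "UTC")
      w <- build_windows(enc_now, extract$observations,
                         features = params$feature)
      w <- normalize_windows(w, params)
      w <- impute_windows(w, params)
      risk <- predict_risk(model, w)
      rdt <- as.data.table(risk)
      latest <- rdt[, .SD[which.max(window_index)], by = encounter_id]
      classifications <- data.frame(
        patient_id = latest$encounter_id,
        group = as.character(assign_risk_group(latest$score, thresholds)),
        stringsAsFactors = FALSE
      )
      n_scored <- nrow(classifications)

      returns <- census$encounter_id[
        !is.na(census$icu_return_ts) &
          census$icu_return_ts > t - 3600 & census$icu_return_ts <= t]
      stepped <- step_alert_engine(alert_state, classifications, returns, t,
                                   config)
      alert_state <- stepped$state
      alerts <- stepped$events
      history <- rbind(history,
                       data.frame(patient_id = classifications$patient_id,
                                  timestamp = t,
                                  group = classifications$group,
                                  stringsAsFactors = FALSE))
    } else {
      # an empty ward still advances the engine clock
      stepped <- step_alert_engine(alert_state, classifications,
                                   character(0), t, config)
      alert_state <- stepped$state
    }
    hr <- as.integer(format(t, "%H", tz = "UTC"))
    if (hr %in% config$census_times) {
      comms <- c(comms, list(build_charge_nurse_census(classifications, t)))
    }
    if (hr == config$digest_time) {
      comms <- c(comms, list(build_palliative_digest(history, t)))
    }
  }

  result <- data.frame(
    cycle_ts = t, status = status, n_scored = n_scored,
    n_alerts = nrow(alerts) / 2L,  # two channel rows per alert
    n_notifications = length(notifications),
    stringsAsFactors = FALSE
  )
  list(result = result, cache = cache, alert_state = alert_state,
       history = history, alerts = alerts, comms = comms,
       notifications = notifications, classifications = classifications)
}

#' Replay the deployment over simulated time
#'
#' Iterates [run_cycle()] hourly from `start` (inclusive) to `end`
#' (exclusive) against a synthetic cohort, applying a fault-injection
#' scenario: planned and unplanned pipeline outage windows are recorded in
#' the run log (planned ones announced once, without per-cycle notification
#' spam) and extract faults exercise the 3-h stale-cache fallback. The full
#' replay is a pure function of the cohort, scenario and configuration —
#' replaying twice yields identical logs.
#'
#' @param encounters,observations The cohort to replay.
#' @param model,params,thresholds Fitted model, normalization parameters and
#'   calibrated thresholds.
#' @param start,end Replay period (UTC; `end` exclusive).
#' @param scenario A [replay_scenario()] or `NULL` for a fault-free run.
#' @param config An [alert_config()].
#' @return List: `run_log` (one row per hour: `cycle_ts`, `status`,
#'   `n_scored`, `n_alerts`, `n_notifications`, `down_hours`), `alert_log`,
#'   `comms` (list of payloads), `notifications`, `history`, and `report`
#'   with the [uptime()] summary and [alert_stats()] over the period.
#' @export
replay <- function(encounters, observations, model, params, thresholds,
                   start, end, scenario = NULL, config = alert_config()) {
  start <- as_utc(start)
  end <- as_utc(end)
  if (end <= start) cw_config_error("replay period is empty")
  if (is.null(scenario)) scenario <- replay_scenario()
  source <- make_cohort_source(encounters, observations,
                               scenario$extract_faults)
  hours <- seq(start, end - 3600, by = "hour")
  outages <- scenario$outages

  state <- new_alert_state()
  history <- data.frame(patient_id = character(0),
                        timestamp = as.POSIXct(character(0), tz = "UTC"),
                        group = character(0), stringsAsFactors = FALSE)
  cache <- NULL
  prev_status <- "ok"
  run_rows <- vector("list", length(hours))
  alert_logs <- list()
  comms <- list()
  notifications <- list()
  announced <- rep(FALSE, if (is.null(outages)) 0L else nrow(outages))

  for (i in seq_along(hours)) {
    t <- hours[i]
    outage_type <- NULL
    down_frac <- 0
    if (!is.null(outages) && nrow(outages)) {
      ov <- pmin(as.numeric(outages$end), as.numeric(t) + 3600) -
        pmax(as.numeric(outages$start), as.numeric(t))
      ov <- pmax(ov, 0) / 3600
      active <- t >= outages$start & t < outages$end
      if (any(active)) {
        j <- which(active)[1]
        outage_type <- outages$type[j]
        down_frac <- min(1, sum(ov))
        if (outage_type == "down_planned" && !announced[j]) {
          notifications <- c(notifications, list(list(
            kind = "planned_downtime_notice", timestamp = t,
            until = outages$end[j])))
          announced[j] <- TRUE
        }
        if (outage_type == "down_unplanned" &&
            !identical(prev_status, "down_unplanned")) {
          notifications <- c(notifications, list(list(
            kind = "unplanned_downtime_start", timestamp = t,
            reason = "pipeline outage")))
        }
      }
    }

    if (!is.null(outage_type)) {
      run_rows[[i]] <- data.frame(cycle_ts = t, status = outage_type,
                                  n_scored = 0L, n_alerts = 0,
                                  n_notifications = 0L,
                                  down_hours = down_frac,
                                  stringsAsFactors = FALSE)
      prev_status <- outage_type
      next
    }

    step <- run_cycle(t, source, cache, model, params, thresholds, state,
                      history, config, prev_status)
    cache <- step$cache
    state <- step$alert_state
    history <- step$history
    if (nrow(step$alerts)) alert_logs[[length(alert_logs) + 1L]] <- step$alerts
    comms <- c(comms, step$comms)
    notifications <- c(notifications, step$notifications)
    row <- step$result
    row$down_hours <- if (row$status == "down_unplanned") 1 else 0
    run_rows[[i]] <- row
    prev_status <- row$status
  }

  run_log <- do.call(rbind, run_rows)
  alert_log <- if (length(alert_logs)) do.call(rbind, alert_logs) else
    empty_alert_log()
  report <- list(
    uptime = uptime(run_log),
    alert_stats = alert_stats(alert_log, as.Date(start),
                              as.Date(end - 3600))
  )
  list(run_log = run_log, alert_log = alert_log, comms = comms,
       notifications = notifications, history = history, report = report)
}
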