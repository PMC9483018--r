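# Stateful alert engine with the four-rule (plus alert-cap) suppression
# protocol, and the communication payload builders.

#' Alerting configuration
#'
#' @param link_url URL appended to pager messages (points end-users to the
#'   clinical pathway description).
#' @param census_times Hours of day (0-23) at which the charge-nurse census
#'   email is emitted; default 07:00 and 19:00, matching 12-hour nursing
#'   shifts.
#' @param digest_time Hour of day of the daily palliative-care digest.
#' @param max_alerts Per-patient cap on total alerts (default 5); set to
#'   `Inf` to restore the uncapped pre-2022 behaviour.
#' @param suppression_h Minimum hours between two alerts for the same
#'   patient (default 48).
#' @param icu_silence_h Hours of silence after a transfer back from the ICU
#'   (default 24).
#' @return A list of class `alert_config`.
#' @export
alert_config <- function(link_url = "http://example.org/pathway",
                         census_times = c(7L, 19L),
                         digest_time = 8L,
                         max_alerts = 5,
                         suppression_h = 48,
                         icu_silence_h = 24) {
  if (max_alerts < 0 || suppression_h < 0 || icu_silence_h < 0) {
    cw_config_error("alert_config rates/limits must be non-negative")
  }
  structure(list(link_url = link_url, census_times = as.integer(census_times),
                 digest_time = as.integer(digest_time),
                 max_alerts = max_alerts, suppression_h = suppression_h,
                 icu_silence_h = icu_silence_h),
            class = "alert_config")
}

#' Fresh alert-engine state
#'
#' One row per patient ever seen: time of last alert, cumulative alert
#' count, last observed risk group ("unseen" before the first
#' classification) and the expiry of any post-ICU silence window. State is
#' per encounter: it starts empty at admission and is discarded at
#' discharge.
#'
#' @return An empty `alert_state` data.frame with attribute `last_t = NA`.
#' @export
new_alert_state <- function() {
  out <- data.frame(
    patient_id = character(0),
    last_alert_ts = as.POSIXct(character(0), tz = "UTC"),
    alert_count = integer(0),
    last_group = character(0),
    icu_silence_until = as.POSIXct(character(0), tz = "UTC"),
    stringsAsFactors = FALSE
  )
  attr(out, "last_t") <- as.POSIXct(NA, tz = "UTC")
  class(out) <- c("alert_state", "data.frame")
  out
}

ensure_state_rows <- function(state, ids) {
  new_ids <- setdiff(ids, state$patient_id)
  if (length(new_ids)) {
    add <- data.frame(
      patient_id = new_ids,
      last_alert_ts = as.POSIXct(NA, tz = "UTC"),
      alert_count = 0L,
      last_group = "unseen",
      icu_silence_until = as.POSIXct(NA, tz = "UTC"),
      stringsAsFactors = FALSE
    )
    a <- attributes(state)
    state <- rbind(as.data.frame(state), add)
    attr(state, "last_t") <- a$last_t
    class(state) <- c("alert_state", "data.frame")
  }
  state
}

#' Advance the alert engine by one classification step
#'
#' Evaluates the alert-fatigue suppression protocol for one time point. An
#' alert fires for a patient if and only if all five predicates hold:
#' \enumerate{
#'   \item the patient's current group is High;
#'   \item the previous group was not High (first High, or a return to High
#'     after dropping to Medium/Low) — a transition during an active 48-h
#'     silence does not re-arm it early, the rules are conjunctive;
#'   \item at least `suppression_h` (48) hours have passed since the
#'     patient's last alert, or the patient has never alerted;
#'   \item fewer than `max_alerts` (5) alerts have been sent for the
#'     patient;
#'   \item any post-ICU silence window (24 h from each return to the ward)
#'     has expired.
#' }
#' Firing updates `last_alert_ts` and `alert_count`; `last_group` is always
#' updated for every classified patient, and suppressed High status remains
#' visible in the census and sign-out channels.
#'
#' @param state An `alert_state` (from [new_alert_state()] or a previous
#'   step).
#' @param classifications data.frame `patient_id`, `group`
#'   (High/Medium/Low); optional `last_name`, `first_name`, `mrn` columns
#'   feed the pager message (the patient id is used when absent).
#' @param icu_returns Character vector of patient ids transferred back from
#'   the ICU at time `t` (each sets a fresh 24-h silence).
#' @param t Current time; must strictly increase between steps.
#' @param config An [alert_config()].
#' @return `list(state, events)`; `events` has one row per alert per
#'   channel (`team_phone` and `charge_nurse_phone`).
#' @export
step_alert_engine <- function(state, classifications, icu_returns = character(0),
                              t, config = alert_config()) {
  t <- as_utc(t)
  last_t <- attr(state, "last_t")
  if (!is.na(last_t) && t <= last_t) {
    cw_config_error("time regression in alert engine: %s after %s",
                    format_iso8601(t), format_iso8601(last_t))
  }
  if (is.data.frame(icu_returns)) icu_returns <- icu_returns$patient_id
  state <- ensure_state_rows(state,
                             union(classifications$patient_id, icu_returns))

  if (length(icu_returns)) {
    i <- match(icu_returns, state$patient_id)
    state$icu_silence_until[i] <- t + config$icu_silence_h * 3600
  }

  events <- list()
  if (nrow(classifications)) {
    i <- match(classifications$patient_id, state$patient_id)
    grp <- as.character(classifications$group)
    fire <- grp == "High" &
      state$last_group[i] != "High" &
      (is.na(state$last_alert_ts[i]) |
         t >= state$last_alert_ts[i] + config$suppression_h * 3600) &
      state$alert_count[i] < config$max_alerts &
      (is.na(state$icu_silence_until[i]) | t >= state$icu_silence_until[i])
    if (any(fire)) {
      rows <- which(fire)
      ids <- classifications$patient_id[rows]
      last <- if (is.null(classifications$last_name)) ids else
        classifications$last_name[rows]
      first <- if (is.null(classifications$first_name)) ids else
        classifications$first_name[rows]
      mrn <- if (is.null(classifications$mrn)) ids else
        classifications$mrn[rows]
      msg <- vapply(seq_along(rows), function(k) {
        format_pager_message(last[k], first[k], mrn[k],
                             link_url = config$link_url)
      }, character(1))
      events <- data.frame(
        patient_id = rep(classifications$patient_id[rows], each = 2L),
        timestamp = t,
        message = rep(msg, each = 2L),
        channel = rep(c("team_phone", "charge_nurse_phone"), length(rows)),
        stringsAsFactors = FALSE
      )
      si <- i[rows]
      state$last_alert_ts[si] <- t
      state$alert_count[si] <- state$alert_count[si] + 1L
    } else {
      events <- empty_alert_log()
    }
    state$last_group[i] <- grp
  } else {
    events <- empty_alert_log()
  }
  attr(state, "last_t") <- t
  class(state) <- c("alert_state", "data.frame")
  list(state = state, events = events)
}

empty_alert_log <- function() {
  data.frame(patient_id = character(0),
             timestamp = as.POSIXct(character(0), tz = "UTC"),
             message = character(0), channel = character(0),
             stringsAsFactors = FALSE)
}

#' Format the high-risk pager message
#'
#' Produces exactly
#' `"[Last, First, MRN] is high risk for transfer to ICU or death. Please
#' refer to LINK for more information."`.
#'
#' @param last_name,first_name,mrn Non-empty patient identifiers.
#' @param link_url URL substituted for LINK.
#' @return The message string.
#' @export
#' @examples
#' format_pager_message("Doe", "Jane", "123", "http://cfg.example")
format_pager_message <- function(last_name, first_name, mrn,
                                 link_url = alert_config()$link_url) {
  for (v in list(last_name = last_name, first_name = first_name, mrn = mrn)) {
    if (length(v) != 1L || is.na(v) || !nzchar(v)) {
      cw_config_error("pager message requires non-empty last name, first name and MRN")
    }
  }
  sprintf("[%s, %s, %s] is high risk for transfer to ICU or death. Please refer to %s for more information.",
          last_name, first_name, mrn, link_url)
}

#' Build the twice-daily charge-nurse census payload
#'
#' One row per patient currently on the ward with their risk group, sorted
#' High, Medium, Low and then by patient id — the charge nurse reads it
#' top-down when assigning bedside nurses. An empty ward yields a valid
#' zero-row payload.
#'
#' @param census data.frame `patient_id`, `group` covering the entire
#'   current ward census.
#' @param t Emission time.
#' @return A list of class `communication_payload` with
#'   `kind = "charge_nurse_census"`, `timestamp`, `rows`.
#' @export
build_charge_nurse_census <- function(census, t) {
  rows <- as.data.frame(census)[, c("patient_id", "group"), drop = FALSE]
  rows$group <- factor(as.character(rows$group),
                       levels = c("High", "Medium", "Low"))
  rows <- rows[order(rows$group, rows$patient_id), , drop = FALSE]
  rows$group <- as.character(rows$group)
  rownames(rows) <- NULL
  structure(list(kind = "charge_nurse_census", timestamp = as_utc(t),
                 rows = rows),
            class = "communication_payload")
}

#' Build the daily palliative-care digest payload
#'
#' Lists exactly those patients whose *first-ever* High classification of
#' the encounter falls in the 24 h ending at `t` (the half-open interval
#' `(t - 24 h, t]`). A patient still High whose first High was earlier than
#' that is not re-listed.
#'
#' @param history data.frame `patient_id`, `timestamp`, `group`: the full
#'   classification history of the current encounters.
#' @param t Emission time.
#' @return A `communication_payload` with `kind = "palliative_digest"` and
#'   rows `patient_id`, `first_high_ts`.
#' @export
build_palliative_digest <- function(history, t) {
  t <- as_utc(t)
  h <- as.data.table(history)[group == "High"]
  if (nrow(h)) {
    firsts <- h[, .(first_high_ts = min(timestamp)), by = patient_id]
    keep <- firsts[first_high_ts > t - 24 * 3600 & first_high_ts <= t]
    setorder(keep, patient_id)
    rows <- as.data.frame(keep)
  } else {
    rows <- data.frame(patient_id = character(0),
                       first_high_ts = as.POSIXct(character(0), tz = "UTC"))
  }
  structure(list(kind = "palliative_digest", timestamp = t, rows = rows),
            class = "communication_payload")
}

#' @export
print.communication_payload <- function(x, ...) {
  cat(sprintf("<communication_payload> %s at %s (%d row(s))\n",
              x$kind, format_iso8601(x$timestamp), nrow(x$rows)))
  if (nrow(x$rows)) print(utils::head(x$rows, 10))
  invisible(x)
}
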