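# Synthetic GIM ward cohorts: encounters, latent severity, observations.

# Hourly Ornstein-Uhlenbeck severity path for one encounter. Mean-reverting
# around 0 for uneventful stays; encounters that end in an outcome revert
# around an elevated level and acquire an additional linear ramp over the
# final 48 h before the outcome, which is the predictable signal the risk
# model is expected to recover.
OU_THETA <- 0.15          # per-hour reversion
OU_SIGMA <- 0.30          # per-hour innovation SD
SEV_BASE_OUTCOME <- 0.6   # chronic elevation of deteriorating patients
SEV_DRIFT_OUTCOME <- 2.2  # additional rise reached at the outcome time
SEV_RAMP_H <- 48          # drift onset, hours before the outcome

simulate_severity <- function(stay_h, has_outcome) {
  grid <- 0:ceiling(stay_h)
  mu <- rep(0, length(grid))
  if (has_outcome) {
    mu <- SEV_BASE_OUTCOME +
      SEV_DRIFT_OUTCOME * pmax(0, 1 - (stay_h - grid) / SEV_RAMP_H)
  }
  stat_sd <- OU_SIGMA / sqrt(2 * OU_THETA)
  innov <- OU_THETA * mu + OU_SIGMA * stats::rnorm(length(grid))
  s0 <- mu[1] + stat_sd * stats::rnorm(1)
  s <- stats::filter(innov, filter = 1 - OU_THETA, method = "recursive",
                     init = s0)
  as.numeric(s)
}

#' Simulate a synthetic GIM cohort
#'
#' Generates a seeded cohort of ward encounters and their long-format
#' vitals/labs observation stream. Admissions arrive as a Poisson process,
#' lengths of stay are log-normal, and each encounter draws one of five
#' competing endpoints (none, death on the ward, ICU transfer, step-up unit
#' transfer, palliative transfer). Encounters with an outcome follow a latent
#' severity process that rises over the 48 h preceding the outcome and shifts
#' the means of severity-loaded features, so a model fitted downstream has a
#' recoverable 48-hour early-warning signal. A configurable fraction of
#' observations is corrupted with data-entry artifacts (impossible magnitudes
#' such as four-digit body temperatures) via [inject_artifacts()].
#'
#' The output is a deterministic function of `config` (including its seed);
#' the caller's RNG state is left untouched.
#'
#' @param config A [sim_config()] object.
#' @return A list with two data.frames:
#'   \describe{
#'     \item{encounters}{`encounter_id`, `admit_ts`, `discharge_ts`, `age`,
#'       `sex` ("F"/"M"), `outcome_type`, `outcome_ts` (NA when
#'       `outcome_type == "none"`), `icu_return_ts` (NA unless the patient
#'       arrived as an ICU step-down).}
#'     \item{observations}{`encounter_id`, `timestamp`, `feature`, `value`,
#'       long format, sorted by encounter and time.}
#'   }
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_encounters = 20, seed = 42))
#' head(cohort$encounters)
#' head(cohort$observations)
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    cw_config_error("'config' must be created with sim_config()")
  }
  with_seed(config$seed, {
    n <- config$n_encounters
    gaps_h <- stats::rexp(n, rate = config$admission_rate / 24)
    admit <- config$start + cumsum(gaps_h) * 3600
    los_h <- pmax(2, stats::rlnorm(n, config$los_meanlog, config$los_sdlog))
    outcome_type <- sample(names(config$outcome_mix), n, replace = TRUE,
                           prob = config$outcome_mix)
    has_outcome <- outcome_type != "none"
    discharge <- admit + los_h * 3600
    outcome_ts <- rep(as.POSIXct(NA, tz = "UTC"), n)
    outcome_ts[has_outcome] <- discharge[has_outcome]
    icu_return <- stats::runif(n) < config$icu_return_rate
    icu_return_ts <- rep(as.POSIXct(NA, tz = "UTC"), n)
    icu_return_ts[icu_return] <- admit[icu_return] +
      stats::runif(sum(icu_return), 0, 2) * 3600

    encounters <- data.frame(
      encounter_id = sprintf("E%05d", seq_len(n)),
      admit_ts = as_utc(admit),
      discharge_ts = as_utc(discharge),
      age = pmin(100, pmax(18, round(stats::rnorm(n, 68, 18)))),
      sex = sample(c("F", "M"), n, replace = TRUE),
      outcome_type = outcome_type,
      outcome_ts = as_utc(outcome_ts),
      icu_return_ts = as_utc(icu_return_ts),
      stringsAsFactors = FALSE
    )

    cat_dt <- as.data.table(config$feature_catalog)
    obs_list <- vector("list", n)
    for (i in seq_len(n)) {
      sev <- simulate_severity(los_h[i], has_outcome[i])
      per_feature <- lapply(seq_len(nrow(cat_dt)), function(j) {
        f <- cat_dt[j]
        # irregular sampling: first draw within one interval of admission,
        # then jittered intervals until the stay ends
        t0 <- stats::runif(1, 0, f$interval_h)
        if (t0 > los_h[i]) return(NULL)
        times <- t0
        repeat {
          nxt <- times[length(times)] + f$interval_h * stats::runif(1, 0.5, 1.5)
          if (nxt > los_h[i]) break
          times <- c(times, nxt)
        }
        sev_at <- sev[pmin(length(sev), floor(times) + 1L)]
        vals <- f$healthy_mean +
          f$healthy_sd * stats::rnorm(length(times)) +
          f$severity_loading * f$healthy_sd * sev_at
        data.table(timestamp_h = times, feature = f$feature, value = vals)
      })
      obs_i <- rbindlist(per_feature)
      if (nrow(obs_i)) obs_i[, encounter_id := encounters$encounter_id[i]]
      obs_list[[i]] <- obs_i
    }
    obs <- rbindlist(obs_list)
    enc_admit <- encounters$admit_ts[match(obs$encounter_id,
                                           encounters$encounter_id)]
    observations <- data.frame(
      encounter_id = obs$encounter_id,
      timestamp = as_utc(enc_admit + obs$timestamp_h * 3600),
      feature = obs$feature,
      value = obs$value,
      stringsAsFactors = FALSE
    )
    observations <- observations[order(observations$encounter_id,
                                       observations$timestamp,
                                       observations$feature), ]
    rownames(observations) <- NULL

    if (config$artifact_rate > 0) {
      observations <- inject_artifacts(
        observations, config$artifact_rate,
        seed = (config$seed %% 1000003L) + 1L,
        catalog = config$feature_catalog
      )
    }
    list(encounters = encounters, observations = observations)
  })
}

#' Corrupt observations with data-entry artifacts
#'
#' Replaces a seeded random fraction of observation values with physically
#' impossible magnitudes, emulating the data-entry errors seen in real ward
#' extracts (e.g. a charted body temperature of 700 or 6932 degrees C, a
#' systolic blood pressure of 16,070). Corrupted values are always outside
#' the feature's plausible physiologic range; all other records are returned
#' untouched and in their original order.
#'
#' @param observations Long-format observation data.frame
#'   (`encounter_id`, `timestamp`, `feature`, `value`).
#' @param artifact_rate Probability in \[0, 1\] that any one record is
#'   corrupted.
#' @param seed Integer seed for the corruption draw.
#' @param catalog Feature catalog supplying plausibility ranges and canonical
#'   artifact magnitudes; see [default_feature_catalog()].
#' @return `observations` with a fraction of values replaced.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_encounters = 5, seed = 1,
#'                                      artifact_rate = 0))
#' dirty <- inject_artifacts(cohort$observations, 0.05, seed = 2)
inject_artifacts <- function(observations, artifact_rate, seed = 1L,
                             catalog = default_feature_catalog()) {
  stopifnot_scalar_prob(artifact_rate, "artifact_rate")
  if (artifact_rate == 0 || nrow(observations) == 0L) return(observations)
  with_seed(seed, {
    hit <- stats::runif(nrow(observations)) < artifact_rate
    idx <- which(hit)
    if (length(idx)) {
      m <- match(observations$feature[idx], catalog$feature)
      if (anyNA(m)) {
        cw_config_error("feature '%s' not present in the artifact catalog",
                        observations$feature[idx][is.na(m)][1])
      }
      hi <- catalog$plausible_high[m]
      example <- catalog$artifact_example[m]
      # half the corruptions reuse the catalog's canonical impossible value
      # when one exists; the rest are order-of-magnitude blow-ups
      use_example <- !is.na(example) & stats::runif(length(idx)) < 0.5
      blown <- hi * 10^stats::runif(length(idx), 1, 3)
      observations$value[idx] <- ifelse(use_example, example, blown)
    }
    observations
  })
}

#' Write / read a cohort as CSV
#'
#' `write_cohort()` serializes a cohort to `encounters.csv` and
#' `observations.csv` in `directory`, with all timestamps rendered as
#' ISO-8601 UTC (`YYYY-MM-DDTHH:MM:SSZ`) and absent timestamps as empty
#' strings. `read_cohort()` reads them back, validating the schema; the
#' round trip is the identity on every field.
#'
#' @param encounters,observations Cohort tables as returned by
#'   [simulate_cohort()].
#' @param directory Target/source directory; created if missing on write.
#' @return `write_cohort()` returns the two file paths invisibly;
#'   `read_cohort()` returns `list(encounters, observations)`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_encounters = 3, seed = 7))
#' d <- tempfile(); write_cohort(cohort$encounters, cohort$observations, d)
#' back <- read_cohort(d)
#' identical(back$encounters$encounter_id, cohort$encounters$encounter_id)
write_cohort <- function(encounters, observations, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  enc_out <- encounters
  for (col in c("admit_ts", "discharge_ts", "outcome_ts", "icu_return_ts")) {
    enc_out[[col]] <- format_iso8601(enc_out[[col]])
  }
  obs_out <- observations
  obs_out$timestamp <- format_iso8601(obs_out$timestamp)
  enc_path <- file.path(directory, "encounters.csv")
  obs_path <- file.path(directory, "observations.csv")
  utils::write.csv(enc_out, enc_path, row.names = FALSE)
  utils::write.csv(obs_out, obs_path, row.names = FALSE)
  invisible(c(encounters = enc_path, observations = obs_path))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  enc_path <- file.path(directory, "encounters.csv")
  obs_path <- file.path(directory, "observations.csv")
  for (p in c(enc_path, obs_path)) {
    if (!file.exists(p)) cw_parse_error("missing cohort file: %s", p)
  }
  enc <- utils::read.csv(enc_path, colClasses = "character")
  required_enc <- c("encounter_id", "admit_ts", "discharge_ts", "age", "sex",
                    "outcome_type", "outcome_ts", "icu_return_ts")
  miss <- setdiff(required_enc, names(enc))
  if (length(miss)) {
    cw_parse_error("encounters.csv is missing required column(s): %s",
                   paste(miss, collapse = ", "))
  }
  obs <- utils::read.csv(obs_path, colClasses = "character")
  required_obs <- c("encounter_id", "timestamp", "feature", "value")
  miss <- setdiff(required_obs, names(obs))
  if (length(miss)) {
    cw_parse_error("observations.csv is missing required column(s): %s",
                   paste(miss, collapse = ", "))
  }

  for (col in c("admit_ts", "discharge_ts", "outcome_ts", "icu_return_ts")) {
    enc[[col]] <- parse_iso8601(enc[[col]])
  }
  age <- suppressWarnings(as.numeric(enc$age))
  if (anyNA(age)) {
    cw_parse_error("non-numeric 'age' in encounters.csv at row %d",
                   which(is.na(age))[1])
  }
  enc$age <- age
  obs$timestamp <- parse_iso8601(obs$timestamp)
  if (anyNA(obs$timestamp)) {
    cw_parse_error("missing 'timestamp' in observations.csv at row %d",
                   which(is.na(obs$timestamp))[1])
  }
  val <- suppressWarnings(as.numeric(obs$value))
  if (anyNA(val)) {
    cw_parse_error("non-numeric 'value' in observations.csv at row %d",
                   which(is.na(val))[1])
  }
  obs$value <- val
  list(encounters = enc, observations = obs)
}
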