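# 6-hour windowing, percentile trimming/normalization, LOCF + mean
# imputation, cohort exclusions and assay conversion.

WINDOW_H <- 6
LABEL_HORIZON_H <- 48

# The four-outcome composite used for training labels.
OUTCOME_LEVELS <- c("death", "icu", "stepup", "palliative")

#' Apply cohort exclusion criteria
#'
#' In training mode, drops encounters whose length of stay is strictly less
#' than `min_los_h` hours (default 8) or strictly greater than `max_los_days`
#' days (default 40); boundary stays are retained. In deploy mode the input
#' is returned unchanged — a live scoring system sees every patient on the
#' ward, so exclusions are a model-development device only.
#'
#' @param encounters Encounter data.frame with `admit_ts`/`discharge_ts`.
#' @param mode `"train"` or `"deploy"`.
#' @param min_los_h,max_los_days Exclusion band bounds.
#' @return The filtered (or untouched) encounter data.frame.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_encounters = 30, seed = 3))
#' nrow(apply_exclusions(cohort$encounters, "train"))
apply_exclusions <- function(encounters, mode = c("train", "deploy"),
                             min_los_h = 8, max_los_days = 40) {
  mode <- match.arg(mode)
  if (mode == "deploy") return(encounters)
  los_h <- hours_between(encounters$discharge_ts, encounters$admit_ts)
  if (any(los_h <= 0, na.rm = TRUE)) {
    cw_config_error("encounter with non-positive length of stay")
  }
  keep <- los_h >= min_los_h & los_h <= max_los_days * 24
  out <- encounters[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

effective_end <- function(encounters) {
  end <- encounters$discharge_ts
  has_out <- !is.na(encounters$outcome_ts)
  end[has_out] <- pmin(end[has_out], encounters$outcome_ts[has_out])
  end
}

#' Build 6-hour feature windows for encounters
#'
#' Converts long-format observations into one row per encounter per 6-hour
#' interval, from the admission timestamp to the first of discharge or
#' outcome. For every feature in `features` each row carries the raw
#' within-window mean (NA when unmeasured; duplicates in a window are
#' averaged), a `<feature>_measured` 0/1 flag, and
#' `<feature>_time_since_measured`: 0 when the feature was measured in the
#' window, otherwise the hours from the window end back to the most recent
#' earlier measurement (hours since admission when the feature has never
#' been measured). A final partial window is
#' emitted. Static covariates (`age`, `sex_female`) and window labels
#' (`outcome_ever`, `outcome_within_48h` under the four-outcome composite)
#' are attached.
#'
#' @param encounters Encounter table (one or more encounters).
#' @param observations Long observation table; rows outside an encounter's
#'   stay are dropped with a warning reporting the count.
#' @param features Character vector of feature names to window; defaults to
#'   the features present in `observations`.
#' @return A data.frame of windows, ordered by encounter and `window_index`
#'   (0-based, contiguous), with attribute `"features"`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_encounters = 5, seed = 11))
#' w <- build_windows(cohort$encounters, cohort$observations)
#' head(w[, 1:6])
build_windows <- function(encounters, observations,
                          features = sort(unique(observations$feature))) {
  if (nrow(encounters) == 0L) cw_config_error("no encounters supplied")
  enc <- as.data.table(encounters)
  enc[, end_ts := effective_end(encounters)]
  enc[, stay_h := hours_between(end_ts, admit_ts)]
  if (any(enc$stay_h <= 0)) cw_config_error("encounter with non-positive stay")
  enc[, n_windows := pmax(1L, as.integer(ceiling(stay_h / WINDOW_H)))]

  obs <- as.data.table(observations)[feature %in% features]
  obs <- merge(obs,
               enc[, .(encounter_id, admit_ts, end_ts, n_windows)],
               by = "encounter_id")
  obs[, rel_h := hours_between(timestamp, admit_ts)]
  outside <- obs$rel_h < 0 |
    hours_between(obs$timestamp, obs$end_ts) > 0
  n_outside <- sum(outside)
  if (n_outside > 0) {
    warning(sprintf("dropped %d observation(s) outside the encounter stay",
                    n_outside), call. = FALSE)
    obs <- obs[!outside]
  }
  obs[, window_index := pmin(as.integer(floor(rel_h / WINDOW_H)),
                             n_windows - 1L)]

  # full grid of windows per encounter
  grid <- enc[, .(window_index = 0:(n_windows - 1L)), by = encounter_id]
  grid <- merge(grid, enc[, .(encounter_id, admit_ts, end_ts, age, sex,
                              outcome_type, outcome_ts)],
                by = "encounter_id")
  grid[, window_start := admit_ts + window_index * WINDOW_H * 3600]
  grid[, window_end := pmin(admit_ts + (window_index + 1) * WINDOW_H * 3600,
                            end_ts)]

  # per-feature aggregates joined onto the grid
  setorder(obs, encounter_id, timestamp)
  for (f in features) {
    of <- obs[feature == f,
              .(value = mean(value), last_ts = timestamp[.N]),
              by = .(encounter_id, window_index)]
    grid <- merge(grid, of, by = c("encounter_id", "window_index"),
                  all.x = TRUE)
    # last measurement at or before each window end (LOCF across windows)
    grid[, measured := as.integer(!is.na(value))]
    grid[, last_seen := as_utc(cummax_na(as.numeric(last_ts))),
         by = encounter_id]
    tsm <- ifelse(is.na(grid$last_seen),
                  hours_between(grid$window_end, grid$admit_ts),
                  pmax(0, hours_between(grid$window_end, grid$last_seen)))
    tsm[grid$measured == 1L] <- 0  # the staleness clock runs only while unmeasured
    setnames(grid, "value", f)
    setnames(grid, "measured", paste0(f, "_measured"))
    grid[, paste0(f, "_time_since_measured") := tsm]
    grid[, c("last_ts", "last_seen") := NULL]
  }

  grid[, sex_female := as.integer(sex == "F")]
  grid[, outcome_ever := as.integer(outcome_type %in% OUTCOME_LEVELS)]
  grid[, outcome_within_48h := as.integer(
    outcome_ever == 1L &
      hours_between(outcome_ts, window_end) <= LABEL_HORIZON_H)]
  grid[is.na(outcome_within_48h), outcome_within_48h := 0L]
  setorder(grid, encounter_id, window_index)
  grid[, c("admit_ts", "end_ts", "sex", "outcome_type", "outcome_ts") := NULL]

  out <- as.data.frame(grid)
  attr(out, "features") <- features
  out
}

# running max that ignores NA (returns NA until first non-NA)
cummax_na <- function(x) {
  x[is.na(x)] <- -Inf
  y <- cummax(x)
  y[y == -Inf] <- NA_real_
  y
}

#' Fit trimming/normalization parameters on training windows
#'
#' Computes, per feature, the empirical 1st and 99th percentiles of the
#' *measured* raw window values (linear-interpolation percentiles), and the
#' mean of the normalized feature on the training windows, which later
#' serves as the mean-imputation constant. Constant features (1st percentile
#' equal to the 99th) are flagged degenerate and normalize to 0.5 by
#' convention, with a warning.
#'
#' @param windows Training windows from [build_windows()] (raw values).
#' @param version Character tag identifying this preprocessing version;
#'   models refuse to score windows normalized under a different tag.
#' @return An object of class `normalization_params`: data.frame
#'   (`feature`, `q01`, `q99`, `train_mean_normalized`, `degenerate`) plus a
#'   `version` attribute.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_encounters = 40, seed = 5))
#' w <- build_windows(cohort$encounters, cohort$observations)
#' fit_normalization(w)
fit_normalization <- function(windows, version = "v1") {
  features <- attr(windows, "features")
  if (is.null(features)) cw_config_error("'windows' lacks a \"features\" attribute")
  rows <- lapply(features, function(f) {
    measured <- windows[[paste0(f, "_measured")]] == 1L
    x <- windows[[f]][measured]
    if (length(x) < 2L) {
      cw_config_error("feature '%s' has fewer than 2 measured values", f)
    }
    q <- stats::quantile(x, c(0.01, 0.99), names = FALSE, type = 7)
    degenerate <- q[1] == q[2]
    if (degenerate) {
      warning(sprintf("feature '%s' is constant on training data; normalizing to 0.5",
                      f), call. = FALSE)
      z <- rep(0.5, length(x))
    } else {
      z <- pmin(1, pmax(0, (x - q[1]) / (q[2] - q[1])))
    }
    data.frame(feature = f, q01 = q[1], q99 = q[2],
               train_mean_normalized = mean(z), degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "version") <- version
  class(out) <- c("normalization_params", "data.frame")
  out
}

#' Normalize raw values for one feature
#'
#' Clips to the training 1st/99th percentiles then maps linearly onto
#' \[0, 1\]; data-entry artifacts (e.g. a temperature of 700) therefore land
#' exactly on 1.0 (or 0.0) rather than distorting the scale. Degenerate
#' features map to 0.5.
#'
#' @param x Numeric vector of raw values (NA passes through).
#' @param params A `normalization_params` object.
#' @param feature Feature name to look up.
#' @return Numeric vector in \[0, 1\] (NA preserved).
#' @export
#' @examples
#' p <- structure(data.frame(feature = "temperature", q01 = 34.8, q99 = 38.3,
#'                           train_mean_normalized = 0.5, degenerate = FALSE),
#'                version = "v1",
#'                class = c("normalization_params", "data.frame"))
#' normalize_feature(c(34.8, 36.55, 700), p, "temperature")
normalize_feature <- function(x, params, feature) {
  i <- match(feature, params$feature)
  if (is.na(i)) cw_config_error("unknown feature '%s' in normalization params", feature)
  if (params$degenerate[i]) {
    out <- ifelse(is.na(x), NA_real_, 0.5)
    return(out)
  }
  pmin(1, pmax(0, (x - params$q01[i]) / (params$q99[i] - params$q01[i])))
}

#' Normalize all feature columns of a window table
#'
#' @param windows Windows from [build_windows()] with raw values.
#' @param params A `normalization_params` object covering every feature.
#' @return Windows with value columns mapped to \[0, 1\] (missing cells stay
#'   NA until [impute_windows()]); tagged with the params' version.
#' @export
normalize_windows <- function(windows, params) {
  features <- attr(windows, "features")
  for (f in features) {
    windows[[f]] <- normalize_feature(windows[[f]], params, f)
  }
  attr(windows, "norm_version") <- attr(params, "version")
  windows
}

#' Impute missing window values (LOCF then training mean)
#'
#' Within each encounter, ordered by `window_index`, every missing normalized
#' value takes the most recent preceding window's value (last observation
#' carried forward); windows before the first measurement take the feature's
#' training-set normalized mean. `_measured` and `_time_since_measured`
#' columns are left untouched — missingness itself is a model feature.
#' Idempotent: imputing twice equals imputing once.
#'
#' @param windows Normalized windows ([normalize_windows()]).
#' @param params The `normalization_params` used to normalize them.
#' @return Windows with no missing value cells.
#' @export
impute_windows <- function(windows, params) {
  features <- attr(windows, "features")
  g <- factor(windows$encounter_id, levels = unique(windows$encounter_id))
  for (f in features) {
    mean_f <- params$train_mean_normalized[match(f, params$feature)]
    windows[[f]] <- unsplit(lapply(split(windows[[f]], g), locf_fill,
                                   lead_value = mean_f), g)
  }
  windows
}

locf_fill <- function(x, lead_value) {
  idx <- cummax_na(ifelse(is.na(x), NA_real_, seq_along(x)))
  out <- ifelse(is.na(idx), lead_value, x[replace(idx, is.na(idx), 1L)])
  out
}

#' Build a model-ready feature matrix in one call
#'
#' Convenience wrapper: windows, then normalization (fitting parameters when
#' none are supplied, i.e. on training data), then imputation.
#'
#' @param encounters,observations Cohort tables.
#' @param params Optional pre-fitted `normalization_params`; when NULL they
#'   are fitted on these windows.
#' @param features Features to include (default: all observed).
#' @param version Version tag used when fitting new params.
#' @return `list(windows, params)`; `windows` is fully imputed and tagged
#'   with the normalization version.
#' @export
prepare_features <- function(encounters, observations, params = NULL,
                             features = sort(unique(observations$feature)),
                             version = "v1") {
  w <- build_windows(encounters, observations, features)
  if (is.null(params)) params <- fit_normalization(w, version = version)
  w <- normalize_windows(w, params)
  w <- impute_windows(w, params)
  list(windows = w, params = params)
}

#' Save / load normalization parameters as JSON
#'
#' Persists the per-feature trimming percentiles, normalized training means,
#' degeneracy flags and the version tag, at full precision.
#'
#' @param params A `normalization_params` object.
#' @param path File path.
#' @return `save_normalization()` the path invisibly; `load_normalization()`
#'   the object.
#' @export
save_normalization <- function(params, path) {
  doc <- list(format = "chartward_normalization",
              version = attr(params, "version"),
              features = as.data.frame(params))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_normalization
#' @export
load_normalization <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    cw_parse_error("cannot parse normalization file '%s': %s",
                                   path, conditionMessage(e))
                  })
  if (!identical(doc$format, "chartward_normalization")) {
    cw_parse_error("'%s' is not a chartward normalization file", path)
  }
  out <- doc$features
  attr(out, "version") <- doc$version
  class(out) <- c("normalization_params", "data.frame")
  out
}

#' Construct an assay conversion map
#'
#' Laboratory assays occasionally change mid-deployment (e.g. a switch to a
#' high-sensitivity troponin assay reporting on a different scale). An assay
#' map lists, per feature, one or more `effective_from` timestamps with a
#' multiplicative `scale` and additive `offset`; observations at or after an
#' entry's timestamp are transformed by `scale * value + offset`, with the
#' latest applicable entry winning when several exist.
#'
#' @param feature Character vector of feature names.
#' @param effective_from Timestamps (coercible to UTC POSIXct).
#' @param scale,offset Numeric transformation parameters.
#' @return An `assay_map` data.frame, sorted by feature and time.
#' @export
#' @examples
#' m <- assay_map("troponin", "2024-02-01", scale = 1000, offset = 0)
assay_map <- function(feature, effective_from, scale = 1, offset = 0) {
  out <- data.frame(feature = feature,
                    effective_from = as_utc(effective_from),
                    scale = scale, offset = offset,
                    stringsAsFactors = FALSE)
  out <- out[order(out$feature, out$effective_from), , drop = FALSE]
  dup <- ave(as.numeric(out$effective_from), out$feature,
             FUN = function(x) duplicated(x))
  if (any(dup > 0)) {
    cw_config_error("assay map has duplicate effective_from timestamps for a feature")
  }
  rownames(out) <- NULL
  class(out) <- c("assay_map", "data.frame")
  out
}

#' Apply an assay conversion map to observations
#'
#' @param observations Long observation table.
#' @param map An [assay_map()]; an empty or NULL map is the identity.
#'   Map entries for features absent from the data are ignored with a
#'   warning.
#' @return Observations with converted values.
#' @export
convert_assay <- function(observations, map) {
  if (is.null(map) || nrow(map) == 0L) return(observations)
  unknown <- setdiff(unique(map$feature), unique(observations$feature))
  if (length(unknown)) {
    warning(sprintf("assay map feature(s) not present in observations: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (f in setdiff(unique(map$feature), unknown)) {
    entries <- map[map$feature == f, , drop = FALSE]
    rows <- which(observations$feature == f)
    # latest entry whose effective_from is <= the observation time
    k <- findInterval(as.numeric(observations$timestamp[rows]),
                      as.numeric(entries$effective_from))
    apply_rows <- rows[k > 0]
    kk <- k[k > 0]
    observations$value[apply_rows] <-
      entries$scale[kk] * observations$value[apply_rows] + entries$offset[kk]
  }
  observations
}
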