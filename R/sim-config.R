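#' Default catalog of simulated vitals and labs
#'
#' One row per simulated feature: how often it is sampled, its distribution
#' in stable patients, how strongly it loads on the latent severity process,
#' and the range of physiologically plausible values used both to detect
#' data-entry artifacts and to generate them. The set mirrors the vitals and
#' labs routinely charted on a general internal medicine (GIM) ward
#' (temperature, blood pressures, respiratory rate, troponin, HbA1c, random
#' glucose, hemoglobin, basophils, ALT); troponin, HbA1c, glucose and ALT are
#' kept on the transformed scale a modelling extract typically stores them in,
#' so healthy means need not look like bedside units.
#'
#' @details
#' Columns:
#' \describe{
#'   \item{feature}{feature name used in observation records.}
#'   \item{kind}{"vital" (sampled every few hours) or "lab" (roughly daily).}
#'   \item{interval_h}{mean sampling interval in hours.}
#'   \item{healthy_mean, healthy_sd}{distribution of the feature in a stable
#'     patient, in the feature's storage units.}
#'   \item{severity_loading}{shift, in healthy SDs per unit of latent
#'     severity, applied to the feature mean as a patient deteriorates.
#'     Sign encodes direction (blood pressure falls, respirations rise).}
#'   \item{plausible_low, plausible_high}{physiologic plausibility range;
#'     values outside it are data-entry artifacts.}
#'   \item{artifact_example}{a canonical impossible value occasionally used
#'     verbatim when corrupting records (e.g. a charted body temperature in
#'     the thousands), NA when none is defined.}
#' }
#'
#' @return A data.frame with one row per feature.
#' @export
#' @examples
#' default_feature_catalog()
default_feature_catalog <- function() {
  data.frame(
    feature = c("temperature", "diastolic_bp", "systolic_bp", "respirations",
                "troponin", "hba1c", "glucose_random", "hemoglobin",
                "basophils", "alt"),
    kind = c("vital", "vital", "vital", "vital",
             "lab", "lab", "lab", "lab", "lab", "lab"),
    interval_h = c(4, 4, 4, 4, 24, 96, 24, 24, 24, 24),
    healthy_mean = c(36.91, 71.49, 129.89, 20.53, 0.28, -2.73, 1.95,
                     106.09, 0.03, 3.38),
    healthy_sd = c(0.75, 11.6, 21, 2.8, 1.6, 0.27, 0.44, 20, 0.03, 1.2),
    severity_loading = c(0.5, -0.5, -0.6, 0.9, 0.7, 0, 0.25, -0.3, 0, 0.2),
    plausible_low = c(30, 20, 50, 4, -4, -4, 0, 30, 0, 0),
    plausible_high = c(43, 160, 260, 60, 9, 3, 5, 220, 3, 10),
    artifact_example = c(6932, NA, 16070, 20147, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic GIM cohort simulator
#'
#' Bundles and validates every knob of the synthetic ward generator. The
#' defaults describe a 78-bed GIM service admitting about 4,000 patients a
#' year: 11 admissions/day and a log-normal length of stay with mean 183 h
#' (about 7.6 days), which by Little's law gives a mean census of about 84
#' concurrent patients.
#'
#' @param n_encounters Number of encounters to generate (positive integer).
#' @param admission_rate Mean admissions per day (Poisson arrivals).
#' @param los_meanlog,los_sdlog Log-normal parameters of length of stay in
#'   hours. Defaults give mean 183 h.
#' @param feature_catalog Data frame as returned by
#'   [default_feature_catalog()].
#' @param outcome_mix Named probabilities over the competing endpoint
#'   \{none, death, icu, stepup, palliative\}; must sum to 1.
#' @param artifact_rate Probability an observation is corrupted by a
#'   data-entry artifact.
#' @param icu_return_rate Fraction of encounters arriving on the ward as
#'   transfers back from the ICU (these carry an `icu_return_ts`).
#' @param start First admission date of the simulation (UTC).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_encounters = 50, seed = 1)
#' str(cfg, max.level = 1)
sim_config <- function(n_encounters,
                       admission_rate = 11,
                       los_meanlog = log(183) - 0.8^2 / 2,
                       los_sdlog = 0.8,
                       feature_catalog = default_feature_catalog(),
                       outcome_mix = c(none = 0.88, death = 0.04, icu = 0.05,
                                       stepup = 0.02, palliative = 0.01),
                       artifact_rate = 0.001,
                       icu_return_rate = 0.05,
                       start = "2024-01-01",
                       seed = 1L) {
  if (!is_scalar_number(n_encounters) || n_encounters < 1 ||
      n_encounters != round(n_encounters)) {
    cw_config_error("'n_encounters' must be a positive integer")
  }
  if (!is_scalar_number(admission_rate) || admission_rate <= 0) {
    cw_config_error("'admission_rate' must be a positive number (admissions/day)")
  }
  if (!is_scalar_number(los_meanlog) || !is_scalar_number(los_sdlog) ||
      los_sdlog < 0) {
    cw_config_error("'los_meanlog'/'los_sdlog' must be finite numbers, sdlog >= 0")
  }
  required_cols <- c("feature", "interval_h", "healthy_mean", "healthy_sd",
                     "severity_loading", "plausible_low", "plausible_high")
  if (!is.data.frame(feature_catalog) || nrow(feature_catalog) == 0L) {
    cw_config_error("'feature_catalog' must be a non-empty data.frame")
  }
  missing_cols <- setdiff(required_cols, names(feature_catalog))
  if (length(missing_cols)) {
    cw_config_error("'feature_catalog' is missing column(s): %s",
                    paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(feature_catalog$feature)) {
    cw_config_error("'feature_catalog' has duplicated feature names")
  }
  if (any(feature_catalog$interval_h <= 0)) {
    cw_config_error("'feature_catalog$interval_h' must be positive")
  }
  outcome_levels <- c("none", "death", "icu", "stepup", "palliative")
  if (is.null(names(outcome_mix)) ||
      !setequal(names(outcome_mix), outcome_levels)) {
    cw_config_error("'outcome_mix' must be named over {%s}",
                    paste(outcome_levels, collapse = ", "))
  }
  outcome_mix <- outcome_mix[outcome_levels]
  if (any(outcome_mix < 0)) cw_config_error("'outcome_mix' has negative entries")
  if (abs(sum(outcome_mix) - 1) > 1e-9) {
    cw_config_error("'outcome_mix' must sum to 1 (got %.12f)", sum(outcome_mix))
  }
  stopifnot_scalar_prob(artifact_rate, "artifact_rate")
  stopifnot_scalar_prob(icu_return_rate, "icu_return_rate")
  if (!is_scalar_number(seed)) cw_config_error("'seed' must be a single integer")

  structure(list(
    n_encounters = as.integer(n_encounters),
    admission_rate = admission_rate,
    los_meanlog = los_meanlog,
    los_sdlog = los_sdlog,
    feature_catalog = feature_catalog,
    outcome_mix = outcome_mix,
    artifact_rate = artifact_rate,
    icu_return_rate = icu_return_rate,
    start = as_utc(start),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d encounters, %.1f admissions/day, mean LOS %.0f h\n",
              x$n_encounters, x$admission_rate,
              exp(x$los_meanlog + x$los_sdlog^2 / 2)))
  cat(sprintf("  outcome mix: %s\n",
              paste(sprintf("%s=%.2f", names(x$outcome_mix), x$outcome_mix),
                    collapse = " ")))
  cat(sprintf("  %d features, artifact rate %.4f, seed %d\n",
              nrow(x$feature_catalog), x$artifact_rate, x$seed))
  invisible(x)
}
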