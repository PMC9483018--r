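# PPV/NPV-targeted conversion of continuous risk scores into
# High / Medium / Low groups.

RISK_LEVELS <- c("Low", "Medium", "High")

encounter_max_scores <- function(timelines) {
  dt <- as.data.table(timelines)
  if (!all(c("encounter_id", "score") %in% names(dt))) {
    cw_config_error("risk timelines need 'encounter_id' and 'score' columns")
  }
  dt[, .(max_score = max(score)), by = encounter_id]
}

align_outcomes <- function(max_scores, outcomes) {
  if (!all(c("encounter_id", "outcome") %in% names(outcomes))) {
    cw_config_error("'outcomes' needs 'encounter_id' and 'outcome' (0/1) columns")
  }
  m <- match(max_scores$encounter_id, outcomes$encounter_id)
  if (anyNA(m)) {
    cw_config_error("missing outcome label for encounter '%s'",
                    max_scores$encounter_id[is.na(m)][1])
  }
  as.integer(outcomes$outcome[m])
}

#' Visit-level positive / negative predictive value
#'
#' Both metrics are computed at the encounter (visit) level from each
#' visit's maximum risk score over its stay. `visit_level_ppv()` is the
#' fraction of alerted encounters (max score at or above `thr_high`) that
#' experienced the outcome; `visit_level_npv()` is the fraction of reassured
#' encounters (max score strictly below `thr_low`) that remained event-free.
#' When no encounter falls on the relevant side of the cutoff the value is
#' undefined and `NA` is returned (never 0).
#'
#' @param timelines Risk timelines: data.frame with `encounter_id` and
#'   `score` (one row per window, e.g. from [predict_risk()]).
#' @param outcomes data.frame with `encounter_id` and 0/1 `outcome`.
#' @param thr_high,thr_low Probability-scale cutoffs.
#' @return A single number in \[0, 1\], or `NA` when undefined.
#' @export
#' @examples
#' tl <- data.frame(encounter_id = letters[1:4], score = c(.9, .8, .2, .1))
#' oc <- data.frame(encounter_id = letters[1:4], outcome = c(1, 0, 0, 0))
#' visit_level_ppv(tl, oc, thr_high = 0.5)
visit_level_ppv <- function(timelines, outcomes, thr_high) {
  ms <- encounter_max_scores(timelines)
  if (nrow(ms) == 0L) cw_config_error("empty risk timelines")
  y <- align_outcomes(ms, outcomes)
  alerted <- ms$max_score >= thr_high
  if (!any(alerted)) return(NA_real_)
  sum(y[alerted] == 1L) / sum(alerted)
}

#' @rdname visit_level_ppv
#' @export
visit_level_npv <- function(timelines, outcomes, thr_low) {
  ms <- encounter_max_scores(timelines)
  if (nrow(ms) == 0L) cw_config_error("empty risk timelines")
  y <- align_outcomes(ms, outcomes)
  reassured <- ms$max_score < thr_low
  if (!any(reassured)) return(NA_real_)
  sum(y[reassured] == 0L) / sum(reassured)
}

#' Calibrate High/Low risk thresholds against PPV and NPV targets
#'
#' Grid search over candidate cutoffs (the unique observed encounter-maximum
#' scores) with seeded, encounter-level K-fold cross-validation. For every
#' candidate cutoff the held-out visit-level PPV (respectively NPV) is
#' computed fold by fold and averaged over folds with a defined value; the
#' selected `thr_high` (`thr_low`) is the cutoff whose cross-validated PPV
#' (NPV) is closest to the target, ties breaking toward the lower cutoff to
#' maximize sensitivity. If the search crosses (`thr_low > thr_high`) both
#' are set to their midpoint with a warning. The cross-validated estimates
#' at the selected cutoffs are recorded as `achieved_ppv` / `achieved_npv`.
#'
#' @param timelines Validation risk timelines (`encounter_id`, `score`).
#' @param outcomes Encounter outcomes (`encounter_id`, 0/1 `outcome`);
#'   both classes must be present.
#' @param target_ppv,target_npv Targets on the probability scale
#'   (defaults 0.40 and 0.99).
#' @param cv_folds Number of encounter-level folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return Object of class `risk_thresholds`: `thr_high`, `thr_low`,
#'   `target_ppv`, `target_npv`, `achieved_ppv`, `achieved_npv`,
#'   `cv_folds`, `seed`.
#' @export
calibrate_thresholds <- function(timelines, outcomes, target_ppv = 0.40,
                                 target_npv = 0.99, cv_folds = 10L,
                                 seed = 1L) {
  stopifnot_scalar_prob(target_ppv, "target_ppv")
  stopifnot_scalar_prob(target_npv, "target_npv")
  ms <- encounter_max_scores(timelines)
  y <- align_outcomes(ms, outcomes)
  if (length(unique(y)) < 2L) {
    cw_config_error("validation set contains a single outcome class")
  }
  n <- nrow(ms)
  cv_folds <- min(as.integer(cv_folds), n)
  fold <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))

  candidates <- sort(unique(ms$max_score))
  if (length(candidates) == 1L) {
    warning("all encounter maximum scores are identical; single candidate cutoff",
            call. = FALSE)
  }

  cv_metric <- function(thr, type) {
    vals <- vapply(seq_len(cv_folds), function(k) {
      s <- ms$max_score[fold == k]
      yy <- y[fold == k]
      if (type == "ppv") {
        sel <- s >= thr
        if (!any(sel)) return(NA_real_)
        sum(yy[sel] == 1L) / sum(sel)
      } else {
        sel <- s < thr
        if (!any(sel)) return(NA_real_)
        sum(yy[sel] == 0L) / sum(sel)
      }
    }, numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }

  pick <- function(type, target) {
    est <- vapply(candidates, cv_metric, numeric(1), type = type)
    ok <- !is.na(est)
    if (!any(ok)) {
      # e.g. all max scores identical: no cutoff puts anyone below/above it
      warning(sprintf("no candidate cutoff yields a defined %s; returning the lowest candidate",
                      toupper(type)), call. = FALSE)
      return(list(thr = candidates[1], achieved = NA_real_))
    }
    dist <- abs(est - target)
    dist[!ok] <- Inf
    best <- which(dist == min(dist))[1]  # ties -> lower cutoff
    list(thr = candidates[best], achieved = est[best])
  }

  high <- pick("ppv", target_ppv)
  low <- pick("npv", target_npv)
  thr_high <- high$thr
  thr_low <- low$thr
  if (thr_low > thr_high) {
    mid <- (thr_low + thr_high) / 2
    warning(sprintf(
      "thr_low (%.4g) exceeded thr_high (%.4g); both set to midpoint %.4g",
      thr_low, thr_high, mid), call. = FALSE)
    thr_low <- thr_high <- mid
  }
  structure(list(
    thr_high = thr_high, thr_low = thr_low,
    target_ppv = target_ppv, target_npv = target_npv,
    achieved_ppv = high$achieved, achieved_npv = low$achieved,
    cv_folds = cv_folds, seed = as.integer(seed)
  ), class = "risk_thresholds")
}

#' @export
print.risk_thresholds <- function(x, ...) {
  cat("<risk_thresholds>\n")
  cat(sprintf("  thr_high = %.6g (CV PPV %.3f, target %.2f)\n",
              x$thr_high, x$achieved_ppv, x$target_ppv))
  cat(sprintf("  thr_low  = %.6g (CV NPV %.3f, target %.2f)\n",
              x$thr_low, x$achieved_npv, x$target_npv))
  invisible(x)
}

#' Assign High / Medium / Low risk groups
#'
#' `score >= thr_high` is High (alerts fire at the threshold),
#' `score < thr_low` is Low, anything between is Medium. Monotone in the
#' score by construction.
#'
#' @param score Numeric vector of probability-scale scores.
#' @param thresholds A `risk_thresholds` object (or list with `thr_high`,
#'   `thr_low`).
#' @return Factor with ordered levels Low < Medium < High.
#' @export
#' @examples
#' thr <- list(thr_high = 0.6, thr_low = 0.2)
#' assign_risk_group(c(0.1, 0.4, 0.6), thr)
assign_risk_group <- function(score, thresholds) {
  if (thresholds$thr_low > thresholds$thr_high) {
    cw_config_error("thr_low must be <= thr_high")
  }
  out <- ifelse(score >= thresholds$thr_high, "High",
                ifelse(score < thresholds$thr_low, "Low", "Medium"))
  factor(out, levels = RISK_LEVELS, ordered = TRUE)
}

#' Save / load calibrated thresholds as JSON
#' @param thresholds A `risk_thresholds` object.
#' @param path File path.
#' @return `save_thresholds()` the path invisibly; `load_thresholds()` the
#'   object.
#' @export
save_thresholds <- function(thresholds, path) {
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_thresholds
#' @export
load_thresholds <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(doc, class = "risk_thresholds")
}

#' Simulate a calibrated validation cohort of risk timelines
#'
#' Generates encounter-level risk timelines whose maximum score is an
#' honestly calibrated outcome probability: each encounter draws a latent
#' risk `s` from a Beta distribution with the requested mean prevalence, its
#' outcome from Bernoulli(`s`), and a short rising score timeline peaking at
#' exactly `s`. Used to exercise the threshold search under conditions where
#' PPV/NPV targets are attainable by construction.
#'
#' @param n_encounters Number of encounters.
#' @param prevalence Mean outcome probability (Beta mean).
#' @param shape1 Beta first shape parameter; the second is derived from the
#'   prevalence. The default (0.35) gives a right tail crossing 0.4 and a
#'   dense mass of near-zero risks, as a ward population does.
#' @param seed Integer seed.
#' @return `list(timelines, outcomes)` in the formats consumed by
#'   [calibrate_thresholds()].
#' @export
simulate_calibrated_scores <- function(n_encounters, prevalence = 0.10,
                                       shape1 = 0.35, seed = 1L) {
  stopifnot_scalar_prob(prevalence, "prevalence")
  shape2 <- shape1 * (1 - prevalence) / prevalence
  with_seed(seed, {
    s <- stats::rbeta(n_encounters, shape1, shape2)
    s <- pmin(pmax(s, 1e-6), 1 - 1e-6)
    outcome <- stats::rbinom(n_encounters, 1L, s)
    n_windows <- sample(3:10, n_encounters, replace = TRUE)
    ids <- sprintf("V%05d", seq_len(n_encounters))
    timelines <- data.frame(
      encounter_id = rep(ids, n_windows),
      window_index = unlist(lapply(n_windows, function(k) 0:(k - 1L))),
      score = unlist(lapply(seq_len(n_encounters), function(i) {
        k <- n_windows[i]
        s[i] * seq(0.5, 1, length.out = k)  # rises to its calibrated max
      })),
      stringsAsFactors = FALSE
    )
    outcomes <- data.frame(encounter_id = ids, outcome = outcome,
                           stringsAsFactors = FALSE)
    list(timelines = timelines, outcomes = outcomes)
  })
}
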