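# Stage 2 of the time-aware model: score-timeline features and a logistic
# layer on top of the per-window MARS score.

STAGE2_FEATURES <- c("current_score", "baseline_score", "delta_prev",
                     "delta_baseline")

#' Derive score-timeline features for one encounter
#'
#' From an ordered per-window score timeline computes, per window: the
#' current score, the baseline score (window 0, the admission window), the
#' change from the previous window, and the change since baseline. At window
#' 0 the baseline equals the current score and both deltas are 0.
#'
#' @param scores Numeric vector of per-window scores, ordered by window
#'   index; must be non-empty.
#' @return data.frame with columns `current_score`, `baseline_score`,
#'   `delta_prev`, `delta_baseline`, one row per window.
#' @export
#' @examples
#' derive_time_features(c(0.1, 0.3, 0.2))
derive_time_features <- function(scores) {
  if (length(scores) == 0L) cw_config_error("empty score timeline")
  data.frame(
    current_score = scores,
    baseline_score = rep(scores[1], length(scores)),
    delta_prev = c(0, diff(scores)),
    delta_baseline = scores - scores[1]
  )
}

# Ridge-stabilized logistic regression via iteratively reweighted least
# squares. The four timeline features are exactly collinear by construction
# (delta_baseline = current - baseline), so a small L2 penalty on the slopes
# (never the intercept) makes the maximum-likelihood problem well posed
# while leaving fitted probabilities essentially unchanged. The same path
# doubles as the fallback under complete separation.
fit_logistic_ridge <- function(X, y, lambda = 1e-4, max_iter = 100L,
                               tol = 1e-10) {
  Xd <- cbind(`(Intercept)` = 1, as.matrix(X))
  ppen <- c(0, rep(lambda, ncol(Xd) - 1L))
  beta <- rep(0, ncol(Xd))
  beta[1] <- stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtWX <- crossprod(Xd, w * Xd) + diag(ppen, ncol(Xd))
    XtWz <- crossprod(Xd, w * z)
    beta_new <- drop(solve(XtWX, XtWz))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(Xd %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(Xd, w * Xd) + diag(ppen, ncol(Xd))
  vcov <- solve(info)
  loglik <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  list(coefficients = stats::setNames(beta, colnames(Xd)),
       vcov = vcov, lambda = lambda, loglik = loglik)
}

window_feature_columns <- function(windows) {
  features <- attr(windows, "features")
  if (is.null(features)) cw_config_error("'windows' lacks a \"features\" attribute")
  c(features, paste0(features, "_measured"),
    paste0(features, "_time_since_measured"), "age", "sex_female")
}

#' Fit the two-stage time-aware deterioration model
#'
#' Stage 1 fits a least-squares MARS ([fit_mars()]) on all processed window
#' features (normalized values, `_measured` flags, `_time_since_measured`
#' clocks, age, sex) against the binary outcome label. Stage 2 then scores
#' every training window, derives score-timeline features per encounter
#' ([derive_time_features()]) and fits a logistic layer on the four timeline
#' features, which supplies the probability link. Training labels use the
#' four-outcome composite (death, ICU transfer, step-up transfer, palliative
#' transfer) via the windows' `outcome_ever` column by default.
#'
#' @param windows Fully imputed, normalized windows ([prepare_features()]).
#' @param label Name of the 0/1 label column (default `"outcome_ever"`).
#' @param stage1 Optionally a pre-fitted `mars_model` to use as stage 1
#'   (stage 2 is then fitted on its scores); useful for experiments with a
#'   fixed basis.
#' @param lambda Stage-2 ridge stabilizer (the four timeline features are
#'   exactly collinear, so a small penalty is always applied).
#' @param ... Passed to [fit_mars()].
#' @return Object of class `time_aware_model`: `stage1` (mars_model),
#'   `stage2` (coefficients, vcov, loglik, loglik_null),
#'   `preprocessing_version`, `feature_columns`, `label`.
#' @export
fit_time_aware <- function(windows, label = "outcome_ever", stage1 = NULL,
                           lambda = 1e-4, ...) {
  y <- windows[[label]]
  if (is.null(y)) cw_config_error("label column '%s' not found", label)
  if (length(unique(y)) < 2L) {
    cw_config_error("training windows contain a single outcome class")
  }
  cols <- window_feature_columns(windows)
  X <- as.matrix(windows[, cols, drop = FALSE])
  if (anyNA(X)) cw_config_error("windows contain missing values; run impute_windows()")
  if (is.null(stage1)) stage1 <- fit_mars(X, y, ...)
  s1 <- predict_mars(stage1, X)
  # split() orders groups by encounter id; realign y the same way
  ord <- order(windows$encounter_id, windows$window_index)
  y_ord <- y[ord]
  tf <- rbindlist(lapply(
    split(seq_along(s1)[ord], windows$encounter_id[ord]),
    function(ix) derive_time_features(s1[ix])))
  stage2 <- fit_logistic_ridge(as.matrix(tf), y_ord, lambda = lambda)
  null_fit <- fit_logistic_ridge(matrix(numeric(0), nrow = length(y_ord),
                                        ncol = 0), y_ord, lambda = lambda)
  structure(list(
    stage1 = stage1,
    stage2 = c(stage2, list(loglik_null = null_fit$loglik)),
    preprocessing_version = attr(windows, "norm_version") %||% "unversioned",
    feature_columns = cols,
    label = label
  ), class = "time_aware_model")
}

#' @export
print.time_aware_model <- function(x, ...) {
  cat(sprintf("<time_aware_model> preprocessing %s, label '%s'\n",
              x$preprocessing_version, x$label))
  cat(sprintf("  stage 1: %d MARS basis functions (GCV %.4g)\n",
              length(x$stage1$terms), x$stage1$gcv))
  cat("  stage 2 logistic coefficients:\n")
  print(round(x$stage2$coefficients, 4))
  invisible(x)
}

#' Score encounters with a time-aware model
#'
#' Produces the per-window risk timeline: stage-1 MARS scores, then the
#' logistic stage over timeline features. Scores are probabilities in (0, 1)
#' and causal — the score of window `w` depends only on windows `0..w` of
#' the same encounter, so appending later windows never changes earlier
#' scores.
#'
#' @param model A `time_aware_model`.
#' @param windows Imputed windows preprocessed under the same normalization
#'   version the model was trained with (mismatch is an error).
#' @return data.frame `encounter_id`, `window_index`, `stage1_score`,
#'   `score` (probability), ordered by encounter and window.
#' @export
predict_risk <- function(model, windows) {
  version <- attr(windows, "norm_version") %||% "unversioned"
  if (!identical(version, model$preprocessing_version)) {
    cw_version_error(
      "windows were preprocessed under version '%s' but the model expects '%s'",
      version, model$preprocessing_version)
  }
  cols <- model$feature_columns
  missing <- setdiff(cols, names(windows))
  if (length(missing)) {
    cw_config_error("windows are missing model feature column(s): %s",
                    paste(missing, collapse = ", "))
  }
  ord <- order(windows$encounter_id, windows$window_index)
  w <- windows[ord, , drop = FALSE]
  s1 <- predict_mars(model$stage1, as.matrix(w[, cols, drop = FALSE]))
  tf <- rbindlist(lapply(split(s1, w$encounter_id), derive_time_features))
  eta <- model$stage2$coefficients[1] +
    as.matrix(tf) %*% model$stage2$coefficients[-1]
  data.frame(
    encounter_id = w$encounter_id,
    window_index = w$window_index,
    stage1_score = s1,
    score = drop(stats::plogis(eta)),
    stringsAsFactors = FALSE
  )
}

#' Save / load a time-aware model as JSON
#'
#' The JSON document stores the stage-1 basis (variable, knot, direction per
#' factor), stage-1 and stage-2 coefficients at full precision, the feature
#' columns and the preprocessing version tag; a round trip reproduces
#' predictions to within 1e-12. `load_model()` refuses a file whose
#' preprocessing version differs from `expected_version` (when supplied) and
#' raises a parse error, never a partial model, on corrupted input.
#'
#' @param model A `time_aware_model`.
#' @param path File path.
#' @param expected_version Optional preprocessing version tag to enforce.
#' @return `save_model()` the path invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  doc <- list(
    format = "chartward_time_aware_model",
    preprocessing_version = model$preprocessing_version,
    label = model$label,
    feature_columns = model$feature_columns,
    stage1 = list(
      terms = lapply(model$stage1$terms, function(fs) {
        lapply(fs, function(f) list(var = f$var, knot = f$knot, sign = f$sign))
      }),
      coefficients = model$stage1$coefficients,
      gcv = model$stage1$gcv,
      gcv_forward = model$stage1$gcv_forward,
      n = model$stage1$n,
      features = model$stage1$features,
      degree = model$stage1$degree,
      gcv_penalty = model$stage1$gcv_penalty
    ),
    stage2 = list(
      coefficients = as.list(model$stage2$coefficients),
      lambda = model$stage2$lambda
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path, expected_version = NULL) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    cw_parse_error("cannot parse model file '%s': %s", path,
                                   conditionMessage(e))
                  })
  if (!identical(doc$format, "chartward_time_aware_model")) {
    cw_parse_error("'%s' is not a chartward model file", path)
  }
  if (!is.null(expected_version) &&
      !identical(doc$preprocessing_version, expected_version)) {
    cw_version_error(
      "model was saved under preprocessing version '%s'; expected '%s'",
      doc$preprocessing_version, expected_version)
  }
  stage1 <- structure(list(
    terms = lapply(doc$stage1$terms, function(fs) {
      lapply(fs, function(f) list(var = as.integer(f$var), knot = f$knot,
                                  sign = f$sign))
    }),
    coefficients = as.numeric(unlist(doc$stage1$coefficients)),
    gcv = doc$stage1$gcv,
    gcv_forward = doc$stage1$gcv_forward,
    n = doc$stage1$n,
    features = as.character(unlist(doc$stage1$features)),
    degree = doc$stage1$degree,
    gcv_penalty = doc$stage1$gcv_penalty
  ), class = "mars_model")
  s2 <- unlist(doc$stage2$coefficients)
  structure(list(
    stage1 = stage1,
    stage2 = list(coefficients = s2, lambda = doc$stage2$lambda),
    preprocessing_version = doc$preprocessing_version,
    feature_columns = as.character(unlist(doc$feature_columns)),
    label = doc$label
  ), class = "time_aware_model")
}
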