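# Multivariate adaptive regression splines, written from first principles:
# greedy forward growth of reflected hinge pairs, then backward deletion
# under generalized cross-validation (GCV).

# A basis function is a list of factors (var index, knot, sign); the
# intercept is the empty product. sign = +1 encodes max(0, x - t),
# sign = -1 encodes max(0, t - x).

eval_basis_term <- function(factors, X) {
  out <- rep(1, nrow(X))
  for (f in factors) {
    out <- out * pmax(0, f$sign * (X[, f$var] - f$knot))
  }
  out
}

eval_basis <- function(terms, Xm) {
  do.call(cbind, lapply(terms, function(fs) eval_basis_term(fs, Xm)))
}

gcv_criterion <- function(rss, n, m, penalty) {
  cost <- m + penalty * (m - 1) / 2
  if (cost >= n) return(Inf)
  (rss / n) / (1 - cost / n)^2
}

#' Fit a multivariate adaptive regression spline
#'
#' Classical least-squares MARS. The forward pass greedily adds reflected
#' hinge pairs `parent * max(0, x_j - t)` and `parent * max(0, t - x_j)`,
#' choosing at each step the (parent basis function, variable, knot) triple
#' that most reduces the residual sum of squares, until `max_terms` basis
#' functions are reached or no candidate reduces the RSS. The backward pass
#' then deletes terms one at a time (never the intercept), at each step
#' removing the term whose deletion minimizes
#' `GCV(M) = (RSS/N) / (1 - C(M)/N)^2` with effective parameter count
#' `C(M) = M + penalty * (M - 1) / 2`, and returns the GCV-minimal submodel
#' encountered. Products are limited to `degree` distinct variables, and a
#' variable never appears twice within one term. Candidate knots are the
#' observed values of each variable, subsampled to at most `max_knots`
#' quantiles. Ties in the forward search break deterministically toward the
#' earliest parent, lowest variable index, then smallest knot.
#'
#' @param X Numeric matrix or data.frame of predictors (no missing values).
#' @param y Numeric response; for a binary outcome the 0/1 labels are fit by
#'   least squares (the classical formulation) and a downstream logistic
#'   stage supplies the probability link, see [fit_time_aware()].
#' @param max_terms Maximum number of basis functions including the
#'   intercept.
#' @param degree Maximum interaction order (1 = additive).
#' @param gcv_penalty Per-knot penalty `d` in `C(M)`; 2-3 is customary
#'   (3 when interactions are allowed).
#' @param max_knots Maximum candidate knots per variable.
#' @param candidate_budget Hard cap on `max_terms` times the total number of
#'   candidate knots; exceeding it raises a resource error rather than
#'   starting an infeasible search.
#' @return An object of class `mars_model`: `terms` (list of basis
#'   functions), `coefficients`, `gcv`, `gcv_forward`, `n`, `features`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(runif(400), ncol = 2)
#' y <- pmax(0, x[, 1] - 0.4) + rnorm(200, sd = 0.01)
#' m <- fit_mars(x, y, max_terms = 11, degree = 1)
#' m
fit_mars <- function(X, y, max_terms = 21L, degree = 2L, gcv_penalty = 3,
                     max_knots = 100L, candidate_budget = 1e6) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || anyNA(y)) cw_config_error("fit_mars requires complete data")
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) cw_config_error("length(y) != nrow(X)")
  if (max_terms < 1L) cw_config_error("'max_terms' must be >= 1")
  features <- colnames(X) %||% paste0("x", seq_len(p))
  colnames(X) <- features

  knot_list <- lapply(seq_len(p), function(j) {
    v <- sort(unique(X[, j]))
    v <- v[-length(v)]  # a hinge at the maximum is identically zero/constant
    if (length(v) > max_knots) {
      v <- unique(stats::quantile(v, probs = seq(0, 1, length.out = max_knots),
                                  names = FALSE, type = 1))
    }
    v
  })
  n_knots_total <- sum(lengths(knot_list))
  if (max_terms * n_knots_total > candidate_budget) {
    cw_resource_error(
      "forward search budget exceeded: max_terms (%d) x candidate knots (%d) > %g",
      max_terms, n_knots_total, candidate_budget)
  }

  terms <- list(list())           # intercept
  B <- matrix(1, n, 1)
  tss <- sum((y - mean(y))^2)
  min_reduction <- max(1e-10 * tss, 1e-12)
  col_tol <- 1e-10 * n

  while (length(terms) + 2L <= max_terms) {
    qrB <- qr(B)
    Q <- qr.Q(qrB)
    r <- y - Q %*% crossprod(Q, y)
    best <- list(reduction = min_reduction, parent = NA, var = NA, knot = NA)
    for (m_i in seq_along(terms)) {
      parent_vars <- vapply(terms[[m_i]], function(f) f$var, integer(1))
      if (length(parent_vars) >= degree) next
      bm <- B[, m_i]
      for (v in setdiff(seq_len(p), parent_vars)) {
        knots <- knot_list[[v]]
        if (!length(knots)) next
        D <- outer(X[, v], knots, "-")
        H1 <- bm * pmax(D, 0)   # pmax(D, 0), not pmax(0, D): keep dim(D)
        H2 <- bm * pmax(-D, 0)
        # residual is orthogonal to Q, so numerators need no projection
        r1 <- drop(crossprod(H1, r))
        r2 <- drop(crossprod(H2, r))
        H1p <- H1 - Q %*% crossprod(Q, H1)
        H2p <- H2 - Q %*% crossprod(Q, H2)
        a <- colSums(H1p^2)
        cc <- colSums(H2p^2)
        b <- colSums(H1p * H2p)
        det <- a * cc - b^2
        red <- numeric(length(knots))
        ok2 <- det > col_tol * pmax(a, cc, 1e-300)
        red[ok2] <- (cc[ok2] * r1[ok2]^2 - 2 * b[ok2] * r1[ok2] * r2[ok2] +
                       a[ok2] * r2[ok2]^2) / det[ok2]
        one1 <- !ok2 & a > col_tol
        red[one1] <- r1[one1]^2 / a[one1]
        one2 <- !ok2 & !one1 & cc > col_tol
        red[one2] <- r2[one2]^2 / cc[one2]
        k_best <- which.max(red)
        if (length(k_best) && red[k_best] > best$reduction * (1 + 1e-9)) {
          best <- list(reduction = red[k_best], parent = m_i, var = v,
                       knot = knots[k_best])
        }
      }
    }
    if (is.na(best$parent)) break
    parent_factors <- terms[[best$parent]]
    bm <- B[, best$parent]
    c1 <- bm * pmax(0, X[, best$var] - best$knot)
    c2 <- bm * pmax(0, best$knot - X[, best$var])
    qrB <- qr(B)
    Q <- qr.Q(qrB)
    for (cand in list(
      list(col = c1, fac = list(var = best$var, knot = best$knot, sign = 1)),
      list(col = c2, fac = list(var = best$var, knot = best$knot, sign = -1)))) {
      cp <- cand$col - Q %*% crossprod(Q, cand$col)
      if (sum(cp^2) > col_tol) {        # singular additions are skipped
        B <- cbind(B, cand$col)
        terms[[length(terms) + 1L]] <- c(parent_factors, list(cand$fac))
        qrB <- qr(B)
        Q <- qr.Q(qrB)
      }
    }
  }

  fit_subset <- function(idx) {
    f <- stats::lm.fit(B[, idx, drop = FALSE], y)
    coefs <- f$coefficients
    coefs[is.na(coefs)] <- 0
    rss <- sum(f$residuals^2)
    list(coefficients = coefs, rss = rss,
         gcv = gcv_criterion(rss, n, length(idx), gcv_penalty))
  }

  full_idx <- seq_along(terms)
  full_fit <- fit_subset(full_idx)
  gcv_forward <- full_fit$gcv
  best_idx <- full_idx
  best_fit <- full_fit
  current_idx <- full_idx
  while (length(current_idx) > 1L) {
    candidates <- current_idx[current_idx != 1L]  # never drop the intercept
    trial <- lapply(candidates, function(drop_i) {
      fit_subset(setdiff(current_idx, drop_i))
    })
    gcvs <- vapply(trial, `[[`, numeric(1), "gcv")
    pick <- which.min(gcvs)
    current_idx <- setdiff(current_idx, candidates[pick])
    if (gcvs[pick] < best_fit$gcv) {
      best_fit <- trial[[pick]]
      best_idx <- current_idx
    }
  }

  structure(list(
    terms = terms[best_idx],
    coefficients = unname(best_fit$coefficients),
    gcv = best_fit$gcv,
    gcv_forward = gcv_forward,
    n = n,
    features = features,
    degree = degree,
    gcv_penalty = gcv_penalty
  ), class = "mars_model")
}

#' @export
print.mars_model <- function(x, ...) {
  cat(sprintf("<mars_model> %d basis functions (incl. intercept), GCV %.4g, n = %d\n",
              length(x$terms), x$gcv, x$n))
  for (i in seq_along(x$terms)) {
    fs <- x$terms[[i]]
    lbl <- if (!length(fs)) "1" else paste(vapply(fs, function(f) {
      if (f$sign > 0) sprintf("h(%s - %.4g)", x$features[f$var], f$knot)
      else sprintf("h(%.4g - %s)", f$knot, x$features[f$var])
    }, character(1)), collapse = " * ")
    cat(sprintf("  %+.4g * %s\n", x$coefficients[i], lbl))
  }
  invisible(x)
}

#' Predict from a fitted MARS model
#'
#' Deterministic linear combination of the retained hinge basis evaluated on
#' new data. `X` must contain every training feature (matched by name when
#' column names are present).
#'
#' @param model A `mars_model`.
#' @param X Matrix or data.frame of predictors.
#' @return Numeric vector of scores, one per row.
#' @export
predict_mars <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(colnames(X))) {
    missing <- setdiff(model$features, colnames(X))
    if (length(missing)) {
      cw_config_error("prediction data is missing feature(s): %s",
                      paste(missing, collapse = ", "))
    }
    X <- X[, model$features, drop = FALSE]
  } else if (ncol(X) != length(model$features)) {
    cw_config_error("prediction data has %d columns; model expects %d",
                    ncol(X), length(model$features))
  }
  drop(eval_basis(model$terms, X) %*% model$coefficients)
}
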