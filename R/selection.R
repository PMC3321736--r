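#' Leave-one-subject-out cross-validation score
#'
#' Subject-level v-fold cross-validation for clustered person-period data:
#' the data are split into one part per subject, so that all of a subject's
#' visit intervals are held out together. For each subject the model is
#' refitted on the remaining subjects' rows (warm-started from the full-data
#' fit) and the held-out subject's Bernoulli log likelihood is accumulated
#' under the refitted hazards. The score is reported as `-2` times the
#' summed held-out log likelihood, so it is directly comparable with the
#' deviance and AIC.
#'
#' When every subject contributes a single row this reduces exactly to
#' ordinary leave-one-out cross-validation.
#'
#' @param data a `person_period` data frame with a `subject_id` column.
#' @param terms model term list (see [dtsgam()]).
#' @param lambda smoothing parameters, as in [dtsgam()].
#' @param on_fold_error `"fallback"` uses the full-data fit for a fold whose
#'   refit fails (for example, a training fold that loses all events),
#'   with a warning; `"abort"` stops.
#' @return Scalar score of class `dtsgam_cv`, with attributes
#'   `"contributions"` (named per-subject held-out log likelihoods summing
#'   to `-score/2`) and `"n_subjects"`.
#' @export
variant_cv <- function(data, terms, lambda,
                       on_fold_error = c("fallback", "abort")) {
  on_fold_error <- match.arg(on_fold_error)
  ids <- unique(data$subject_id)
  if (length(ids) < 2L) stop("need at least two subjects for cross-validation")
  design <- build_design(data, terms)
  full <- dtsgam(data, design, lambda = lambda)
  lam <- full$lambda
  contrib <- numeric(length(ids))
  names(contrib) <- as.character(ids)
  for (k in seq_along(ids)) {
    hold <- data$subject_id == ids[k]
    Ztr <- design$Z[!hold, , drop = FALSE]
    ytr <- full$y[!hold]
    core <- tryCatch(
      fit_pirls(Ztr, ytr, design$penalties, design$blocks, lam,
                beta_init = full$coefficients),
      error = function(e) NULL)
    if (is.null(core) || !all(is.finite(core$beta))) {
      if (on_fold_error == "abort")
        stop("refit failed for held-out subject ", ids[k])
      warning("refit failed for held-out subject ", ids[k],
              "; using the full-data fit for this fold")
      beta_k <- full$coefficients
    } else beta_k <- core$beta
    contrib[k] <- partial_loglik(beta_k, design$Z[hold, , drop = FALSE],
                                 full$y[hold])
  }
  structure(-2 * sum(contrib), contributions = contrib,
            n_subjects = length(ids), class = "dtsgam_cv")
}

#' @export
print.dtsgam_cv <- function(x, ...) {
  cat(sprintf("Leave-one-subject-out CV score (-2 log likelihood): %.4f over %d subjects\n",
              unclass(x)[1], attr(x, "n_subjects")))
  invisible(x)
}

#' Select smoothing parameters on a grid by subject-level cross-validation
#'
#' Evaluates [variant_cv()] exhaustively over a grid of smoothing-parameter
#' combinations (the Cartesian product of per-term candidate values) and
#' returns the minimizing combination. Ties are broken deterministically
#' toward the largest parameters (the smoother model).
#'
#' @param data a `person_period` data frame.
#' @param terms model term list.
#' @param grid either a numeric vector of candidates shared by all smooth
#'   terms, or a named list of candidate vectors (one per smooth term,
#'   named by covariate). Defaults to powers of ten from 1e-4 to 1e2.
#' @param verbose print per-point progress?
#' @return A list of class `dtsgam_cv_grid`: `grid` (data frame of
#'   combinations with a `score` column), `lambda_opt` (named optimum), and
#'   `score_opt`.
#' @export
grid_search_cv <- function(data, terms, grid = 10^seq(-4, 2), verbose = FALSE) {
  if (inherits(terms, "term_spec")) terms <- list(terms)
  smooth_vars <- vapply(Filter(function(t) t$kind == "smooth", terms),
                        function(t) t$var, "")
  if (!length(smooth_vars)) stop("no smooth terms to select lambda for")
  if (!is.list(grid)) grid <- stats::setNames(
    rep(list(as.numeric(grid)), length(smooth_vars)), smooth_vars)
  if (!all(smooth_vars %in% names(grid)))
    stop("grid must supply candidates for every smooth term")
  combos <- expand.grid(grid[smooth_vars], KEEP.OUT.ATTRS = FALSE)
  if (nrow(combos) == 0L) stop("empty smoothing-parameter grid")
  scores <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    lam <- as.numeric(combos[i, ])
    scores[i] <- as.numeric(variant_cv(data, terms, lambda = lam))
    if (verbose)
      message(sprintf("lambda = (%s): CV = %.4f",
                      paste(signif(lam, 3), collapse = ", "), scores[i]))
  }
  best <- which(scores <= min(scores) + 1e-12)
  if (length(best) > 1L) {   # smoother model wins ties
    smoothness <- rowSums(log(as.matrix(combos[best, , drop = FALSE])))
    best <- best[which.max(smoothness)]
  }
  out <- list(grid = cbind(combos, score = scores),
              lambda_opt = stats::setNames(as.numeric(combos[best, ]),
                                           smooth_vars),
              score_opt = scores[best])
  class(out) <- "dtsgam_cv_grid"
  out
}

#' @export
print.dtsgam_cv_grid <- function(x, ...) {
  cat("Smoothing-parameter grid search (leave-one-subject-out CV)\n")
  cat("Optimum:", paste(sprintf("%s = %g", names(x$lambda_opt), x$lambda_opt),
                        collapse = ", "),
      sprintf("  (CV = %.4f)\n", x$score_opt))
  invisible(x)
}

#' Generalized cross-validation score
#'
#' The deviance-based GCV criterion `N * Dev / (N - edf)^2`, an
#' approximation to leave-one-row-out cross-validation. Provided as a
#' comparator to the subject-level CV of [variant_cv()], which respects the
#' clustering of rows within subjects.
#'
#' @param fit a `dtsgam_fit`.
#' @return The GCV score.
#' @export
gcv_score <- function(fit) {
  N <- fit$n_rows
  if (fit$edf >= N) stop("effective df must be below the row count")
  N * fit$deviance / (N - fit$edf)^2
}

#' Akaike information criterion on the deviance scale
#'
#' `AIC = Dev + 2 * edf`, with the effective degrees of freedom playing the
#' role of the parameter count. The numeric form
#' `aic_from_deviance(dev, edf)` supports reconstructing the criterion from
#' reported deviance / residual-df summaries.
#'
#' @param fit a `dtsgam_fit`.
#' @return The AIC value.
#' @export
model_aic <- function(fit) aic_from_deviance(fit$deviance, fit$edf)

#' @rdname model_aic
#' @param dev deviance.
#' @param edf effective degrees of freedom.
#' @export
aic_from_deviance <- function(dev, edf) dev + 2 * edf

#' Likelihood-ratio test between nested penalized fits
#'
#' Compares a nested model (for example, a linear effect of a covariate)
#' with a fuller model (a spline effect of the same covariate) by the
#' deviance difference, referred to a chi-square distribution whose degrees
#' of freedom are the difference in effective degrees of freedom. Fractional
#' df are supported through the continuous (gamma) form of the chi-square.
#'
#' @param fit_nested,fit_full fitted `dtsgam_fit` objects, nested in that
#'   order.
#' @return A list of class `dtsgam_lr`: `delta` (deviance reduction), `df`
#'   (edf difference) and `p_value`.
#' @export
lr_test <- function(fit_nested, fit_full) {
  out <- lr_from_deviances(fit_nested$deviance, fit_full$deviance,
                           fit_full$edf - fit_nested$edf)
  class(out) <- "dtsgam_lr"
  out
}

#' @rdname lr_test
#' @param dev_nested,dev_full deviances of the nested and full models.
#' @param df degrees of freedom of the comparison (may be fractional).
#' @export
lr_from_deviances <- function(dev_nested, dev_full, df) {
  delta <- dev_nested - dev_full
  if (delta < -1e-6)
    warning("deviance increased in the fuller model (delta = ",
            signif(delta, 4), "); models may not be nested or a fit failed")
  p <- if (df <= 0) 1 else stats::pchisq(max(delta, 0), df = df,
                                         lower.tail = FALSE)
  list(delta = delta, df = df, p_value = p)
}

#' @export
print.dtsgam_lr <- function(x, ...) {
  cat(sprintf("LR test: delta deviance = %.4f on %.3f df, p = %.4g\n",
              x$delta, x$df, x$p_value))
  invisible(x)
}

#' Approximate per-term significance tests
#'
#' For each model term, a Wald-type chi-square statistic on the term's
#' coefficient block, using the frequentist covariance of the penalized
#' estimator and the term's effective degrees of freedom as the reference
#' df. The tests are approximate (penalization biases the block toward
#' zero) and intended for screening covariates.
#'
#' @param fit a `dtsgam_fit`.
#' @return Named vector of p-values, one per term.
#' @export
term_pvalues <- function(fit) {
  blocks <- fit$design$blocks
  Vb <- fit$cov_penalized %*% fit$ZtWZ %*% fit$cov_penalized
  p <- vapply(seq_along(blocks), function(i) {
    idx <- blocks[[i]]
    b <- fit$coefficients[idx]
    if (all(b == 0)) return(1)
    Vt <- Vb[idx, idx, drop = FALSE]
    stat <- tryCatch(drop(crossprod(b, solve(Vt, b))), error = function(e) {
      ev <- eigen(Vt, symmetric = TRUE)
      keep <- ev$values > max(ev$values) * 1e-10
      bt <- crossprod(ev$vectors[, keep, drop = FALSE], b)
      sum(bt^2 / ev$values[keep])
    })
    df <- max(fit$edf_term[[names(blocks)[i]]], 1e-8)
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  }, 0)
  names(p) <- names(blocks)
  p
}
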