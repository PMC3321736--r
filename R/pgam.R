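#' Bernoulli partial log likelihood of a person-period table
#'
#' The log likelihood summed over the expanded rows:
#' `sum(y * log(h) + (1 - y) * log(1 - h))` with
#' `h = plogis(Z %*% beta)`. The per-subject decomposition over visit
#' intervals is algebraically identical to this row sum, so the table is
#' treated as independent Bernoulli trials for estimation.
#'
#' @param beta coefficient vector.
#' @param Z model matrix.
#' @param y binary response vector.
#' @return The scalar log likelihood.
#' @export
partial_loglik <- function(beta, Z, y) {
  eta <- drop(Z %*% beta)
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  # numerically stable: y*eta - log(1 + exp(eta))
  sum(y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))
}

# Penalized IRLS (Fisher scoring with step halving) for the Bernoulli
# person-period likelihood. S_list holds the constrained penalty matrix per
# term (NULL for unpenalized terms), blocks the column indices, lambda one
# value per term (ignored where S is NULL).
fit_pirls <- function(Z, y, S_list, blocks, lambda,
                      beta_init = NULL, tol = 1e-8, maxit = 200L,
                      ridge = 1e-10) {
  q <- ncol(Z)
  Slam <- matrix(0, q, q)
  for (i in seq_along(S_list)) {
    if (!is.null(S_list[[i]]) && lambda[i] > 0) {
      idx <- blocks[[i]]
      Slam[idx, idx] <- Slam[idx, idx] + lambda[i] * S_list[[i]]
    }
  }
  beta <- if (is.null(beta_init)) rep(0, q) else beta_init
  pen_obj <- function(b) partial_loglik(b, Z, y) - 0.5 * drop(crossprod(b, Slam %*% b))
  obj <- pen_obj(beta)
  converged <- FALSE
  iter <- 0L
  ridge_used <- FALSE
  for (iter in seq_len(maxit)) {
    eta <- drop(Z %*% beta)
    h <- stats::plogis(eta)
    w <- pmax(h * (1 - h), 1e-12)
    u <- drop(crossprod(Z, y - h)) - drop(Slam %*% beta)  # penalized score
    H <- crossprod(Z * sqrt(w)) + Slam
    step <- tryCatch(solve(H, u), error = function(e) {
      ridge_used <<- TRUE
      solve(H + diag(ridge * (1 + diag(H)), q), u)
    })
    # step halving on the penalized objective
    new_obj <- -Inf
    for (half in 0:30) {
      cand <- beta + step / 2^half
      new_obj <- tryCatch(pen_obj(cand), error = function(e) -Inf)
      if (is.finite(new_obj) && new_obj >= obj - 1e-14) break
    }
    if (!is.finite(new_obj)) break
    beta <- cand
    if (abs(new_obj - obj) < tol * (abs(obj) + 0.1)) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  eta <- drop(Z %*% beta)
  h <- stats::plogis(eta)
  w <- pmax(h * (1 - h), 1e-12)
  ZtWZ <- crossprod(Z * sqrt(w))
  Hinv <- tryCatch(solve(ZtWZ + Slam), error = function(e) {
    ridge_used <<- TRUE
    solve(ZtWZ + Slam + diag(ridge * (1 + diag(ZtWZ)), q))
  })
  Fmat <- Hinv %*% ZtWZ                       # influence matrix
  edf_col <- diag(Fmat)
  ll <- partial_loglik(beta, Z, y)
  if (max(abs(eta)) > 15 &&
      ((any(y == 1) && min(h[y == 1]) > 1 - 1e-6) ||
       (any(y == 0) && max(h[y == 0]) < 1e-6)))
    warning("fitted hazards pinned at 0/1; possible (quasi-)separation")
  if (!converged)
    warning("penalized IRLS did not converge in ", maxit, " iterations")
  list(beta = beta, hazard = h, loglik = ll, deviance = -2 * ll,
       edf = sum(edf_col), edf_col = edf_col,
       cov_penalized = Hinv, ZtWZ = ZtWZ, Slam = Slam,
       iterations = iter, converged = converged, ridge_used = ridge_used,
       gradient_norm = sqrt(sum((drop(crossprod(Z, y - h)) - drop(Slam %*% beta))^2)))
}

#' Fit a penalized additive discrete-time hazard model
#'
#' Models the discrete hazard of the person-period table on the logit scale
#' as an additive combination of the supplied terms, maximizing the
#' penalized Bernoulli log likelihood
#' `lnL(beta) - 0.5 * sum(lambda_i * integral(s_i'')^2)` by penalized
#' iteratively reweighted least squares. The deviance is `-2 lnL(beta)`
#' (the saturated binary model has log likelihood zero), and the effective
#' degrees of freedom are the trace of the influence matrix
#' `solve(Z'WZ + S_lambda) %*% Z'WZ` at convergence.
#'
#' @param data a `person_period` data frame from [expand_person_period()].
#' @param terms list of [smooth_term()] / [linear_term()] specs.
#' @param lambda smoothing parameters: either one nonnegative value per
#'   term (values for linear terms are ignored) or a single value recycled
#'   across the smooth terms.
#' @param beta_init optional warm-start coefficients.
#' @param tol relative convergence tolerance on the penalized objective.
#' @param maxit maximum IRLS iterations.
#' @return An object of class `dtsgam_fit` with components `coefficients`,
#'   `lambda`, `fitted_hazard`, `loglik`, `deviance`, `edf` (total),
#'   `edf_term` (per term, intercept included under `"(Intercept)"`),
#'   `residual_df` (`N - edf`), `design`, and convergence diagnostics.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_subjects = 60, seed = 7))
#' pp <- expand_person_period(cohort$subjects)
#' fit <- dtsgam(pp, list(linear_term("age"), smooth_term("bili", 5)),
#'               lambda = 1)
#' fit$deviance
#' @export
dtsgam <- function(data, terms, lambda = 1, beta_init = NULL,
                   tol = 1e-8, maxit = 200L) {
  if (inherits(terms, "term_spec")) terms <- list(terms)
  design <- if (inherits(terms, "dtsgam_design")) terms
            else build_design(data, terms)
  y <- data$y
  stopifnot(!is.null(y), all(y %in% c(0, 1)))
  n_terms <- length(design$terms)
  is_smooth <- !vapply(design$penalties, is.null, TRUE)
  if (length(lambda) == 1L) {
    lam <- rep(0, n_terms)
    lam[is_smooth] <- lambda
  } else if (length(lambda) == n_terms) {
    lam <- lambda
    lam[!is_smooth] <- 0
  } else if (length(lambda) == sum(is_smooth)) {
    lam <- rep(0, n_terms)
    lam[is_smooth] <- lambda
  } else stop("lambda must have length 1, one per term, or one per smooth term")
  if (any(lam < 0)) stop("smoothing parameters must be nonnegative")

  core <- fit_pirls(design$Z, y, design$penalties, design$blocks, lam,
                    beta_init = beta_init, tol = tol, maxit = maxit)
  edf_term <- c("(Intercept)" = core$edf_col[1],
                vapply(seq_len(n_terms), function(i)
                  sum(core$edf_col[design$blocks[[i]]]), 0))
  names(edf_term)[-1L] <- names(design$blocks)
  lambda_out <- lam
  names(lambda_out) <- names(design$blocks)
  structure(list(coefficients = core$beta, lambda = lambda_out,
                 fitted_hazard = core$hazard, loglik = core$loglik,
                 deviance = core$deviance, edf = core$edf,
                 edf_term = edf_term, residual_df = nrow(data) - core$edf,
                 n_rows = nrow(data), design = design, y = y,
                 cov_penalized = core$cov_penalized, ZtWZ = core$ZtWZ,
                 subject_id = data$subject_id,
                 iterations = core$iterations, converged = core$converged,
                 gradient_norm = core$gradient_norm),
            class = "dtsgam_fit")
}

#' @export
print.dtsgam_fit <- function(x, ...) {
  cat("Penalized discrete-time hazard model\n")
  cat("Terms: ", paste(names(x$edf_term)[-1L], collapse = " + "), "\n", sep = "")
  cat(sprintf("N = %d rows; deviance = %.2f; edf = %.3f; residual df = %.2f\n",
              x$n_rows, x$deviance, x$edf, x$residual_df))
  smooth <- x$lambda[x$lambda > 0]
  if (length(smooth))
    cat("lambda:", paste(sprintf("%s = %g", names(smooth), smooth),
                         collapse = ", "), "\n")
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
summary.dtsgam_fit <- function(object, ...) {
  out <- list(edf_term = object$edf_term, lambda = object$lambda,
              deviance = object$deviance, edf = object$edf,
              residual_df = object$residual_df,
              aic = model_aic(object), gcv = gcv_score(object),
              term_pvalues = term_pvalues(object))
  class(out) <- "summary.dtsgam_fit"
  out
}

#' @export
print.summary.dtsgam_fit <- function(x, ...) {
  cat(sprintf("deviance = %.3f   edf = %.3f   residual df = %.3f\n",
              x$deviance, x$edf, x$residual_df))
  cat(sprintf("AIC = %.3f   GCV = %.5g\n", x$aic, x$gcv))
  tab <- data.frame(edf = round(x$edf_term[-1L], 3),
                    lambda = unname(x$lambda),
                    p_value = signif(x$term_pvalues, 3))
  print(tab)
  invisible(x)
}

#' @export
deviance.dtsgam_fit <- function(object, ...) object$deviance

#' @export
logLik.dtsgam_fit <- function(object, ...) {
  structure(object$loglik, df = object$edf, class = "logLik")
}

#' @export
coef.dtsgam_fit <- function(object, ...) object$coefficients

#' Predict discrete hazards from a fitted model
#'
#' Evaluates the fitted additive predictor at new person-period rows, using
#' the knots and centering constraints frozen at fit time. Covariate values
#' outside a smooth's boundary knots are clamped to the boundary (with a
#' warning).
#'
#' @param object a `dtsgam_fit`.
#' @param newdata data frame with the model covariates (and `midpoint` if
#'   the model has a `"time"` term). Defaults to the training rows.
#' @param type `"hazard"` for probabilities, `"link"` for the logit.
#' @param ... unused.
#' @return Numeric vector of per-row hazards (or linear predictors).
#' @export
predict.dtsgam_fit <- function(object, newdata = NULL,
                               type = c("hazard", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- drop(object$design$Z %*% object$coefficients)
  } else {
    Z <- design_rows(object$design, newdata)
    eta <- drop(Z %*% object$coefficients)
  }
  if (type == "link") eta else stats::plogis(eta)
}
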