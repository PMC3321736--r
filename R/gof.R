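#' Bootstrap goodness-of-fit test for the deviance
#'
#' For ungrouped binary responses the deviance has no usable chi-square
#' reference distribution, so the critical value is obtained by a
#' nonparametric bootstrap: subjects (whole visit histories, so the
#' within-subject event/censoring structure is preserved) are resampled with
#' replacement, the model is refitted to each bootstrap cohort with the same
#' smoothing parameters and frozen basis, and the replicate deviances
#' `Dev(b) = -2 lnL(X*(b); beta*(b))` are collected. The `j`th order
#' statistic of the `B` replicates estimates the quantile of order
#' `j / (B + 1)`; the `100 (1 - alpha)` percentile is the critical point,
#' and an observed deviance above it indicates poor fit.
#'
#' @param data a `person_period` data frame with `subject_id`.
#' @param terms model term list (see [dtsgam()]).
#' @param lambda smoothing parameters, held fixed across replicates.
#' @param B number of bootstrap replicates (at least 39 for the 5% point
#'   to be an order statistic).
#' @param alpha significance level.
#' @param seed integer seed; replicate resamples are drawn from
#'   deterministic per-replicate substreams so results are reproducible.
#' @param type `"case"` (default) resamples whole subjects with
#'   replacement. Note that this centers the replicate deviances near the
#'   observed one, so the test is very conservative when the model is
#'   correct: it flags only gross lack of fit. `"parametric"` instead
#'   simulates replicate responses row-wise from the fitted hazards at the
#'   observed design (a GLM-style parametric reference conditioning on the
#'   observed visit structure), which gives a calibrated null distribution
#'   for the deviance.
#' @param min_effective_frac abort if fewer than this fraction of
#'   replicates yield a successful refit.
#' @return A list of class `dtsgam_gof`: `observed_deviance`, `samples`
#'   (sorted replicate deviances), `critical_value`, `rank`, `alpha`, `B`,
#'   `B_effective`, and the logical `reject` (poor fit).
#' @export
bootstrap_gof <- function(data, terms, lambda, B = 400, alpha = 0.05,
                          seed = 1, type = c("case", "parametric"),
                          min_effective_frac = 0.8) {
  type <- match.arg(type)
  if (B < ceiling(1 / alpha) - 1)
    stop("B too small for the requested alpha: need B >= ", ceiling(1 / alpha) - 1)
  design <- build_design(data, terms)
  full <- dtsgam(data, design, lambda = lambda)
  ids <- unique(data$subject_id)
  n <- length(ids)
  rows_of <- split(seq_len(nrow(data)), factor(data$subject_id, levels = ids))
  set.seed(as.integer(seed %% .Machine$integer.max))
  rep_seeds <- sample.int(.Machine$integer.max, B)
  dev_b <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    if (type == "case") {
      draw <- sample.int(n, n, replace = TRUE)
      idx <- unlist(rows_of[draw], use.names = FALSE)
      Zb <- design$Z[idx, , drop = FALSE]
      yb <- full$y[idx]
    } else {
      Zb <- design$Z
      yb <- stats::rbinom(nrow(Zb), 1, full$fitted_hazard)
    }
    core <- tryCatch(
      fit_pirls(Zb, yb, design$penalties, design$blocks, full$lambda,
                beta_init = full$coefficients),
      error = function(e) NULL)
    if (!is.null(core) && all(is.finite(core$beta)) && core$converged)
      dev_b[b] <- core$deviance
  }
  ok <- !is.na(dev_b)
  if (sum(ok) < min_effective_frac * B)
    stop("too many bootstrap refits failed (", B - sum(ok), " of ", B, ")")
  if (any(!ok))
    warning(B - sum(ok), " bootstrap replicate(s) failed to refit and were dropped")
  samples <- sort(dev_b[ok])
  Beff <- length(samples)
  j <- round((1 - alpha) * (Beff + 1))
  j <- min(max(j, 1L), Beff)
  crit <- samples[j]
  structure(list(observed_deviance = full$deviance, samples = samples,
                 critical_value = crit, rank = j, alpha = alpha,
                 B = B, B_effective = Beff, type = type,
                 reject = full$deviance > crit, fit = full),
            class = "dtsgam_gof")
}

#' @export
print.dtsgam_gof <- function(x, ...) {
  cat(sprintf("Bootstrap goodness of fit (B = %d, %d effective)\n",
              x$B, x$B_effective))
  cat(sprintf("observed deviance = %.2f; %.0f%% critical value = %.2f (rank %d)\n",
              x$observed_deviance, 100 * (1 - x$alpha), x$critical_value, x$rank))
  cat(if (x$reject) "=> deviance exceeds the critical value: the model fits poorly\n"
      else "=> deviance below the critical value: no evidence of lack of fit\n")
  invisible(x)
}

#' Histogram bin counts for the bootstrap deviance distribution
#'
#' Convenience summary for plotting the replicate deviances alongside the
#' observed value and the critical point.
#'
#' @param gof a `dtsgam_gof`.
#' @param bins number of bins.
#' @return Data frame with `mid`, `lower`, `upper`, `count`.
#' @export
gof_histogram <- function(gof, bins = 20) {
  h <- graphics::hist(gof$samples, breaks = bins, plot = FALSE)
  data.frame(mid = h$mids, lower = utils::head(h$breaks, -1),
             upper = h$breaks[-1], count = h$counts)
}
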