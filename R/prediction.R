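#' Per-subject survival curve from fitted interval hazards
#'
#' Converts the fitted discrete hazards along one subject's visit-interval
#' path into a survival curve: `S(t_l) = prod(1 - h_i, i <= l)`, evaluated
#' at the interval end points. Survival before the first interval is 1.
#'
#' @param fit a `dtsgam_fit`.
#' @param path data frame of one subject's person-period rows (columns
#'   `t_start`, `t_end`, `midpoint` and the model covariates), in interval
#'   order.
#' @param hazards optional hazard vector overriding the model prediction
#'   (used mainly for testing the product algebra).
#' @return A list of class `survival_curve`: `t_start`, `t_end`, `hazard`,
#'   `survival` (at interval ends), and `subject_id` when present.
#' @export
survival_curve <- function(fit, path, hazards = NULL) {
  if (nrow(path) == 0L) stop("empty covariate path")
  if (is.null(hazards)) hazards <- predict(fit, path)
  stopifnot(length(hazards) == nrow(path), all(hazards >= 0 & hazards <= 1))
  structure(list(subject_id = if (!is.null(path$subject_id)) path$subject_id[1] else NA,
                 t_start = path$t_start, t_end = path$t_end,
                 hazard = hazards, survival = cumprod(1 - hazards)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Survival curve over", length(x$hazard), "intervals\n")
  print(data.frame(t_start = x$t_start, t_end = x$t_end,
                   hazard = round(x$hazard, 4),
                   survival = round(x$survival, 4)))
  invisible(x)
}

#' Conditional short-term survival probability
#'
#' `Pr(t, dt) = S(t + dt) / S(t)`: the probability of surviving `dt`
#' further given survival to `t`. On the discrete interval grid this is the
#' product of `1 - h_i` over the intervals whose start falls in
#' `[t, t + dt)`, which makes the probability exactly multiplicative over
#' adjacent windows: `Pr(t, d1 + d2) = Pr(t, d1) * Pr(t + d1, d2)`.
#'
#' @param curve a `survival_curve`.
#' @param t window start (days).
#' @param dt window length (days); defaults to six months (182.5).
#' @return Probability in `[0, 1]`.
#' @export
conditional_survival <- function(curve, t, dt = 182.5) {
  stopifnot(dt >= 0)
  if (dt == 0) return(1)
  span <- curve$t_start >= t - 1e-9 & curve$t_start < t + dt - 1e-9
  prod(1 - curve$hazard[span])
}

# Extend a subject's interval path dt days past its end: future intervals
# reuse the last observed interval's length and carry the last visit's
# covariates forward (the minimal extrapolation assumption).
extend_path <- function(path, until) {
  last <- path[nrow(path), , drop = FALSE]
  len <- last$t_end - last$t_start
  while (path$t_end[nrow(path)] < until) {
    nxt <- last
    nxt$t_start <- path$t_end[nrow(path)]
    nxt$t_end <- nxt$t_start + len
    nxt$midpoint <- (nxt$t_start + nxt$t_end) / 2
    if ("interval" %in% names(nxt)) nxt$interval <- path$interval[nrow(path)] + 1L
    if ("y" %in% names(nxt)) nxt$y <- 0
    path <- rbind(path, nxt)
  }
  path
}

#' Short-term survival ahead of each clinic visit
#'
#' For every visit of one subject, the probability of surviving the next
#' `dt` days from the visit date, with the interval grid extended past the
#' observed follow-up where needed (future intervals reuse the last
#' interval's length; covariates are carried forward from the last visit).
#'
#' @param fit a `dtsgam_fit`.
#' @param path one subject's person-period rows.
#' @param dt look-ahead window in days (default six months).
#' @return Data frame with `interval`, `t` (visit day) and `pr` columns.
#' @export
visit_ahead_survival <- function(fit, path, dt = 182.5) {
  ext <- extend_path(path, max(path$t_start) + dt + 1e-9)
  curve <- survival_curve(fit, ext)
  data.frame(interval = seq_len(nrow(path)), t = path$t_start,
             pr = vapply(path$t_start, function(t0)
               conditional_survival(curve, t0, dt), 0))
}

#' Group-averaged short-term survival by clinic visit
#'
#' Averages the `dt`-day-ahead survival probability over the subjects still
#' under observation at each visit index, separately for the dead and
#' censored groups: the visit-`l` average is the mean of `Pr(l, l + dt)`
#' over the subjects in the group with at least `l` visits.
#'
#' @param fit a `dtsgam_fit`.
#' @param data the `person_period` table (must carry the
#'   `"terminal_status"` attribute from [expand_person_period()]).
#' @param dt look-ahead window in days.
#' @param groups which terminal-status groups to summarize.
#' @return Data frame with `group`, `interval`, `n` (subjects contributing)
#'   and `mean_pr`.
#' @export
group_average <- function(fit, data, dt = 182.5,
                          groups = c("dead", "censored")) {
  status <- attr(data, "terminal_status")
  if (is.null(status)) stop("data must carry the terminal_status attribute")
  per_subject <- lapply(split(seq_len(nrow(data)), data$subject_id),
                        function(idx) visit_ahead_survival(fit, data[idx, , drop = FALSE], dt))
  out <- list()
  for (g in groups) {
    in_g <- names(per_subject)[status[names(per_subject)] == g]
    if (!length(in_g)) next
    max_l <- max(vapply(per_subject[in_g], nrow, 0L))
    for (l in seq_len(max_l)) {
      pr <- unlist(lapply(per_subject[in_g], function(d)
        if (nrow(d) >= l) d$pr[l] else NULL))
      if (!length(pr)) next
      out[[length(out) + 1L]] <- data.frame(group = g, interval = l,
                                            n = length(pr), mean_pr = mean(pr))
    }
  }
  do.call(rbind, out)
}

#' Per-visit quantiles of short-term survival
#'
#' Distributional summary (box-plot style) of the `dt`-day-ahead survival
#' probabilities across subjects at each visit index.
#'
#' @inheritParams group_average
#' @param probs quantile probabilities.
#' @param group restrict to one terminal-status group (`NULL` = all).
#' @return Data frame with one row per visit index and one column per
#'   quantile, plus `n`.
#' @export
visit_quantiles <- function(fit, data, dt = 182.5,
                            probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                            group = "dead") {
  status <- attr(data, "terminal_status")
  per_subject <- lapply(split(seq_len(nrow(data)), data$subject_id),
                        function(idx) visit_ahead_survival(fit, data[idx, , drop = FALSE], dt))
  if (!is.null(group)) {
    keep <- names(per_subject)[status[names(per_subject)] %in% group]
    per_subject <- per_subject[keep]
  }
  if (!length(per_subject)) stop("no subjects in the requested group")
  max_l <- max(vapply(per_subject, nrow, 0L))
  rows <- lapply(seq_len(max_l), function(l) {
    pr <- unlist(lapply(per_subject, function(d)
      if (nrow(d) >= l) d$pr[l] else NULL))
    if (!length(pr)) return(NULL)
    q <- stats::quantile(pr, probs = probs)
    cbind(data.frame(interval = l, n = length(pr)),
          as.data.frame(as.list(stats::setNames(q, paste0("q", 100 * probs)))))
  })
  do.call(rbind, rows)
}
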