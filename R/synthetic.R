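#' Configuration for a simulated visit-structured cohort
#'
#' Defines the data-generating process for a synthetic longitudinal cohort
#' shaped like sequential liver-disease follow-up data: subjects return at
#' about six months, twelve months, and then yearly (with jitter); age,
#' prothrombin time and bilirubin evolve slowly between visits; each
#' subject ends in death, censoring, or optionally liver transplantation.
#' At every visit interval the death indicator is drawn with probability
#' `plogis(intercept + f_age(age) + f_pro(pro) + f_bili(bili))` evaluated
#' at that interval's covariates, so the generated table follows the
#' discrete-time hazard model exactly and the true per-row hazards are
#' recoverable.
#'
#' @param n_subjects cohort size.
#' @param seed integer seed.
#' @param first_visits days of the early visits after entry (defaults to
#'   six and twelve months).
#' @param yearly_gap nominal gap between later visits (days).
#' @param visit_jitter half-width (days) of the uniform jitter on later
#'   visit days.
#' @param admin_years range (years) of the uniform administrative
#'   end-of-follow-up per subject.
#' @param censor_prob per-interval probability of loss to follow-up.
#' @param intercept baseline logit of the per-interval death probability.
#' @param f_age,f_pro,f_bili effect functions on the logit scale; the
#'   default bilirubin effect is log-shaped (steep at low values,
#'   saturating at high values), so spline-versus-linear comparisons have a
#'   genuinely nonlinear truth to find.
#' @param age_mean,age_sd baseline age distribution (years).
#' @param pro_mean,pro_sd,pro_drift,pro_noise prothrombin time (seconds):
#'   baseline distribution, per-year drift, and per-year random-walk sd.
#' @param logbili_mean,logbili_sd,bili_drift,bili_noise log-bilirubin
#'   (mg/dL): baseline distribution, per-year drift, and per-year
#'   random-walk sd.
#' @param transplant `NULL` for no competing event, or a list with
#'   `bili_threshold` and `prob`: at any interval where bilirubin exceeds
#'   the threshold, the subject is transplanted with that probability (and
#'   leaves the cohort without the death event, the competing-risk coding).
#' @return A list of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_subjects = 312, seed = 1,
                          first_visits = c(182.5, 365), yearly_gap = 365,
                          visit_jitter = 30, admin_years = c(3, 12),
                          censor_prob = 0.03,
                          intercept = -2.9,
                          f_age = function(a) 0.035 * (a - 50),
                          f_pro = function(p) 0.30 * (p - 10.7),
                          f_bili = function(b) 1.2 * (log(b) - log(3)),
                          age_mean = 50, age_sd = 10,
                          pro_mean = 10.7, pro_sd = 1.0,
                          pro_drift = 0.08, pro_noise = 0.35,
                          logbili_mean = log(1.8), logbili_sd = 1.0,
                          bili_drift = 0.15, bili_noise = 0.35,
                          transplant = NULL) {
  cfg <- as.list(environment())
  stopifnot(n_subjects >= 1, all(diff(first_visits) > 0), yearly_gap > 0,
            visit_jitter >= 0, censor_prob >= 0, censor_prob < 1,
            admin_years[1] > 0, admin_years[2] >= admin_years[1])
  class(cfg) <- "cohort_config"
  cfg
}

#' Simulate a longitudinal cohort with known hazard structure
#'
#' Generates subject visit histories under the data-generating process of a
#' [cohort_config()]. Each subject's visit days are laid out first (entry,
#' the early visits, then jittered yearly visits up to an administrative
#' end); covariates follow their random walks across visits; then, interval
#' by interval, death is drawn with the true model probability, followed by
#' possible loss to follow-up or transplantation. Exactly one terminal
#' outcome ends each subject.
#'
#' @param config a [cohort_config()].
#' @return A list with `subjects` (a `subject_histories` object, ready for
#'   [expand_person_period()]) and `truth`: the config, the per-row true
#'   hazards (`rows` data frame with `subject_id`, `interval`, `true_h`,
#'   `eta`), and the true effect functions.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_subjects = 25, seed = 3))
#' cohort$subjects
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(config$seed %% .Machine$integer.max))
  rows <- list()
  truth_rows <- list()
  for (d in seq_len(config$n_subjects)) {
    admin_day <- stats::runif(1, config$admin_years[1], config$admin_years[2]) * 365
    # visit schedule: entry, early visits, then jittered yearly visits
    days <- c(0, config$first_visits)
    nxt <- config$first_visits[length(config$first_visits)] + config$yearly_gap
    while (nxt < admin_day - config$visit_jitter - 1) {
      days <- c(days, nxt + stats::runif(1, -config$visit_jitter,
                                         config$visit_jitter))
      nxt <- nxt + config$yearly_gap
    }
    days <- days[days < admin_day - 1]
    ends <- c(days[-1], admin_day)

    age0 <- stats::rnorm(1, config$age_mean, config$age_sd)
    pro <- stats::rnorm(1, config$pro_mean, config$pro_sd)
    logbili <- stats::rnorm(1, config$logbili_mean, config$logbili_sd)
    status <- "censored"
    subj_rows <- list()
    for (l in seq_along(days)) {
      if (l > 1) {
        dt_yr <- (days[l] - days[l - 1]) / 365
        pro <- pro + config$pro_drift * dt_yr +
          stats::rnorm(1, 0, config$pro_noise * sqrt(dt_yr))
        logbili <- logbili + config$bili_drift * dt_yr +
          stats::rnorm(1, 0, config$bili_noise * sqrt(dt_yr))
        pro <- max(pro, 8.5)
      }
      age <- age0 + days[l] / 365
      bili <- exp(logbili)
      eta <- config$intercept + config$f_age(age) + config$f_pro(pro) +
        config$f_bili(bili)
      h <- stats::plogis(eta)
      subj_rows[[l]] <- data.frame(id = d, day = days[l], age = age,
                                   pro = pro, bili = bili)
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(subject_id = d, interval = l, eta = eta, true_h = h)
      died <- stats::runif(1) < h
      if (died) { status <- "dead"; futime <- ends[l]; break }
      if (!is.null(config$transplant) &&
          bili > config$transplant$bili_threshold &&
          stats::runif(1) < config$transplant$prob) {
        status <- "transplanted"; futime <- ends[l]; break
      }
      if (l < length(days) && stats::runif(1) < config$censor_prob) {
        status <- "censored"; futime <- ends[l]; break
      }
      futime <- ends[l]
    }
    df <- do.call(rbind, subj_rows)
    df$futime <- futime
    df$status <- unname(c(censored = 0, transplanted = 1, dead = 2)[status])
    rows[[d]] <- df
  }
  long <- do.call(rbind, rows)
  subjects <- as_subject_histories(
    long, visit_schema(covariates = c("age", "pro", "bili")))
  if (!is.null(config$transplant))
    subjects <- encode_transplant(subjects)
  list(subjects = subjects,
       truth = list(config = config,
                    rows = do.call(rbind, truth_rows),
                    f_age = config$f_age, f_pro = config$f_pro,
                    f_bili = config$f_bili))
}
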