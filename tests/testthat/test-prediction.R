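# A fabricated curve over a regular grid, bypassing model prediction.
toy_curve <- function(hazards, len = 100) {
  n <- length(hazards)
  path <- data.frame(t_start = (0:(n - 1)) * len, t_end = (1:n) * len,
                     midpoint = ((0:(n - 1)) + 0.5) * len)
  survival_curve(NULL, path, hazards = hazards)
}

test_that("survival curves are cumulative products of one minus hazard", {
  expect_equal(toy_curve(rep(0, 4))$survival, rep(1, 4))
  expect_equal(toy_curve(c(0.5, 0.5))$survival, c(0.5, 0.25))
  set.seed(44)
  h <- runif(30)
  curve <- toy_curve(h)
  expect_equal(curve$survival, exp(cumsum(log1p(-h))), tolerance = 1e-12)
  # telescoping identity
  expect_equal(curve$survival / c(1, head(curve$survival, -1)), 1 - h,
               tolerance = 1e-12)
  expect_true(all(diff(curve$survival) <= 0))
  expect_error(survival_curve(NULL, data.frame()[0, ]), "empty")
})

test_that("conditional survival is a window product and multiplicative", {
  h <- c(0.1, 0.2, 0.3, 0.15)
  curve <- toy_curve(h, len = 100)
  expect_equal(conditional_survival(curve, 50, 0), 1)
  # one full interval at constant hazard
  ch <- toy_curve(rep(0.2, 5), len = 100)
  expect_equal(conditional_survival(ch, 100, 100), 0.8)
  # enumeration oracle: intervals starting within [t, t + dt)
  direct <- function(curve, t, dt)
    prod(1 - curve$hazard[curve$t_start >= t & curve$t_start < t + dt])
  set.seed(3)
  for (r in 1:20) {
    t0 <- runif(1, 0, 300); dt <- runif(1, 0, 200)
    expect_equal(conditional_survival(curve, t0, dt), direct(curve, t0, dt),
                 tolerance = 1e-12)
    d1 <- runif(1, 0, dt)
    expect_equal(conditional_survival(curve, t0, dt),
                 conditional_survival(curve, t0, d1) *
                   conditional_survival(curve, t0 + d1, dt - d1),
                 tolerance = 1e-12)
  }
})

test_that("model-based curves and look-ahead windows agree with the fit", {
  pp <- small_pp(80, seed = 15)
  fit <- dtsgam(pp, list(linear_term("age"), smooth_term("bili", 5)),
                lambda = 1)
  one <- pp[pp$subject_id == pp$subject_id[1], ]
  curve <- survival_curve(fit, one)
  expect_equal(curve$hazard, predict(fit, one), tolerance = 1e-12)
  expect_equal(curve$survival, cumprod(1 - predict(fit, one)))
  ahead <- visit_ahead_survival(fit, one, dt = 182.5)
  expect_equal(nrow(ahead), nrow(one))
  expect_true(all(ahead$pr >= 0 & ahead$pr <= 1))
})

test_that("group averages reduce to the subject for singleton groups", {
  pp <- small_pp(60, seed = 19)
  fit <- dtsgam(pp, list(linear_term("bili")), lambda = 0)
  status <- attr(pp, "terminal_status")
  dead_ids <- names(status)[status == "dead"]
  one_id <- dead_ids[1]
  sub <- pp[pp$subject_id == one_id, ]
  sub_attr <- pp[pp$subject_id == one_id, ]
  attr(sub_attr, "terminal_status") <- status[one_id]
  ga <- group_average(fit, sub_attr, dt = 182.5, groups = "dead")
  ahead <- visit_ahead_survival(fit, sub, dt = 182.5)
  expect_equal(ga$mean_pr, ahead$pr, tolerance = 1e-12)
  expect_true(all(ga$n == 1))

  # two subjects: arithmetic mean at shared visit indices
  two_ids <- dead_ids[1:2]
  sub2 <- pp[pp$subject_id %in% two_ids, ]
  attr(sub2, "terminal_status") <- status[two_ids]
  ga2 <- group_average(fit, sub2, dt = 182.5, groups = "dead")
  a1 <- visit_ahead_survival(fit, pp[pp$subject_id == two_ids[1], ], 182.5)
  a2 <- visit_ahead_survival(fit, pp[pp$subject_id == two_ids[2], ], 182.5)
  l_shared <- min(nrow(a1), nrow(a2))
  expect_equal(ga2$mean_pr[seq_len(l_shared)],
               (a1$pr[seq_len(l_shared)] + a2$pr[seq_len(l_shared)]) / 2,
               tolerance = 1e-12)

  # full-cohort brute-force averaging oracle
  ga_all <- group_average(fit, pp, dt = 182.5)
  for (g in unique(ga_all$group)) {
    ids_g <- names(status)[status == g]
    aheads <- lapply(ids_g, function(id)
      visit_ahead_survival(fit, pp[pp$subject_id == id, ], 182.5))
    for (l in unique(ga_all$interval[ga_all$group == g])) {
      prs <- unlist(lapply(aheads, function(a) if (nrow(a) >= l) a$pr[l]))
      expect_equal(ga_all$mean_pr[ga_all$group == g & ga_all$interval == l],
                   mean(prs), tolerance = 1e-12)
    }
  }
})

test_that("dying subjects show declining short-term survival before death", {
  cohort <- simulate_cohort(cohort_config(n_subjects = 150, seed = 23))
  pp <- expand_person_period(cohort$subjects)
  fit <- dtsgam(pp, list(linear_term("age"), smooth_term("bili")), lambda = 1)
  status <- attr(pp, "terminal_status")
  dead_ids <- names(status)[status == "dead"]
  diffs <- vapply(dead_ids, function(id) {
    sub <- pp[pp$subject_id == id, ]
    if (nrow(sub) < 2) return(NA_real_)
    a <- visit_ahead_survival(fit, sub, dt = 182.5)
    a$pr[nrow(a)] - a$pr[1]
  }, 0)
  expect_lt(stats::median(diffs, na.rm = TRUE), 0)
})

test_that("per-visit quantile tables summarize the cohort distribution", {
  pp <- small_pp(60, seed = 19)
  fit <- dtsgam(pp, list(linear_term("bili")), lambda = 0)
  q <- visit_quantiles(fit, pp, group = "dead")
  expect_true(all(q$q50 >= q$q25 & q$q25 >= q$q5))
  expect_true(all(q$n >= 1))
})
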