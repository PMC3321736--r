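test_that("subject-level CV reduces to ordinary LOO for singleton subjects", {
  set.seed(31)
  df <- data.frame(subject_id = 1:50, age = rnorm(50, 50, 8),
                   bili = rlnorm(50), y = rbinom(50, 1, 0.3))
  terms <- list(linear_term("age"), linear_term("bili"))
  score <- variant_cv(df, terms, lambda = 0)
  # ordinary LOO oracle: explicit row loop with the same warm start
  design <- build_design(df, terms)
  full <- dtsgam(df, terms, lambda = 0)
  loo <- 0
  for (r in seq_len(nrow(df))) {
    core <- dtsgam:::fit_pirls(design$Z[-r, , drop = FALSE], df$y[-r],
                               design$penalties, design$blocks,
                               rep(0, 2), beta_init = full$coefficients)
    loo <- loo + partial_loglik(core$beta, design$Z[r, , drop = FALSE],
                                df$y[r])
  }
  expect_equal(as.numeric(score), -2 * loo, tolerance = 1e-10)
  # contributions decompose the score
  expect_equal(-2 * sum(attr(score, "contributions")), as.numeric(score))
  # one fold cross-checked against an independent glm refit
  g <- stats::glm(y ~ age + bili, family = binomial, data = df[-1, ])
  h1 <- stats::predict(g, newdata = df[1, ], type = "response")
  ll1 <- df$y[1] * log(h1) + (1 - df$y[1]) * log(1 - h1)
  expect_equal(unname(attr(score, "contributions")[1]), unname(ll1),
               tolerance = 1e-6)
})

test_that("three-subject toy CV matches a hand-rolled refit-and-predict loop", {
  df <- data.frame(subject_id = rep(1:3, times = c(2, 3, 1)),
                   y = c(0, 1, 0, 0, 0, 1))
  score <- variant_cv(df, list(), lambda = 0)
  hand <- 0
  for (d in 1:3) {
    train <- df[df$subject_id != d, ]
    test <- df[df$subject_id == d, ]
    p <- mean(train$y)  # intercept-only MLE is the event fraction
    hand <- hand + sum(test$y * log(p) + (1 - test$y) * log(1 - p))
  }
  expect_equal(as.numeric(score), -2 * hand, tolerance = 1e-6)
})

test_that("duplicated subjects contribute symmetric CV terms", {
  set.seed(14)
  base <- data.frame(subject_id = rep(1:6, each = 3),
                     bili = rlnorm(18), y = 0)
  base$y[c(3, 9, 18)] <- 1
  dup <- base; dup$subject_id <- dup$subject_id + 100
  both <- rbind(base, dup)
  score <- variant_cv(both, list(linear_term("bili")), lambda = 0)
  contrib <- attr(score, "contributions")
  expect_equal(unname(contrib[as.character(1:6)]),
               unname(contrib[as.character(101:106)]), tolerance = 1e-8)
})

test_that("grid search returns the minimizing lambda with smoother tie-break", {
  pp <- small_pp(40, seed = 3)
  terms <- list(smooth_term("bili", 5))
  g1 <- grid_search_cv(pp, terms, grid = 1)
  expect_equal(unname(g1$lambda_opt), 1)
  expect_equal(g1$score_opt, as.numeric(variant_cv(pp, terms, lambda = 1)),
               tolerance = 1e-9)
  g3 <- grid_search_cv(pp, terms, grid = c(0.01, 1, 100))
  expect_true(all(g3$score_opt <= g3$grid$score + 1e-12))
  # duplicated candidate values tie exactly; the larger lambda wins
  gt <- grid_search_cv(pp, terms, grid = c(2, 2))
  expect_equal(unname(gt$lambda_opt), 2)
  expect_error(grid_search_cv(pp, list(linear_term("bili"))), "no smooth")
})

test_that("GCV and AIC follow their defining arithmetic", {
  pp <- small_pp(50, seed = 6)
  fit <- dtsgam(pp, list(smooth_term("bili", 5)), lambda = 1)
  N <- nrow(pp)
  expect_equal(gcv_score(fit), N * fit$deviance / (N - fit$edf)^2)
  expect_equal(model_aic(fit), fit$deviance + 2 * fit$edf)
  expect_equal(aic_from_deviance(10, 0), 10)  # edf-free limit
  # GCV increases with edf at fixed deviance
  f1 <- list(n_rows = N, deviance = 100, edf = 5)
  f2 <- list(n_rows = N, deviance = 100, edf = 10)
  expect_true(gcv_score(f2) > gcv_score(f1))
  f0 <- list(n_rows = N, deviance = 0, edf = 5)
  expect_equal(gcv_score(f0), 0)
})

test_that("LR tests compare nested fits on the deviance scale", {
  pp <- small_pp(120, seed = 8)
  f_lin <- dtsgam(pp, list(linear_term("bili")), lambda = 0)
  f_sm <- dtsgam(pp, list(smooth_term("bili")), lambda = 0.5)
  lr <- lr_test(f_lin, f_sm)
  expect_equal(lr$delta, f_lin$deviance - f_sm$deviance)
  expect_equal(lr$df, f_sm$edf - f_lin$edf)
  expect_true(lr$p_value >= 0 && lr$p_value <= 1)
  # identical models: delta 0, p 1
  lr0 <- lr_test(f_sm, f_sm)
  expect_equal(lr0$delta, 0)
  expect_equal(lr0$p_value, 1)
  # fractional df use the continuous chi-square
  expect_equal(lr_from_deviances(105, 100, 0.973)$p_value,
               stats::pchisq(5, 0.973, lower.tail = FALSE))
  expect_warning(lr_from_deviances(100, 105, 2), "increased")
})

test_that("term-level Wald screens detect a strong effect and stay in [0, 1]", {
  cohort <- simulate_cohort(cohort_config(n_subjects = 200, seed = 17))
  pp <- expand_person_period(cohort$subjects)
  fit <- dtsgam(pp, list(linear_term("age"), smooth_term("bili")), lambda = 1)
  p <- term_pvalues(fit)
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(p[["s(bili)"]], 0.001)  # strong simulated effect
  # all-zero coefficient block gives p = 1
  fit0 <- fit
  fit0$coefficients[fit0$design$blocks[["s(bili)"]]] <- 0
  expect_equal(unname(term_pvalues(fit0)[["s(bili)"]]), 1)
})

test_that("null spline-vs-linear tests are approximately calibrated", {
  # true linear effect: the smooth-vs-linear LR test should reject rarely
  rejections <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    cfg <- cohort_config(n_subjects = 60, seed = 900 + r,
                         f_bili = function(b) 0.15 * (b - 3),
                         logbili_sd = 0.6)
    pp <- expand_person_period(simulate_cohort(cfg)$subjects)
    f_lin <- dtsgam(pp, list(linear_term("bili")), lambda = 0)
    f_sm <- dtsgam(pp, list(smooth_term("bili", 5)), lambda = 1)
    lr <- suppressWarnings(lr_test(f_lin, f_sm))
    if (is.finite(lr$p_value) && lr$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections / n_rep, 0.2)
})
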