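# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the basis oracle is the textbook Cox-de Boor
# recursion, the likelihood oracle a plain row loop.

# Cox-de Boor recursion for one B-spline basis function value.
cdb_one <- function(x, knots, j, degree) {
  if (degree == 0) {
    # right-closed at the final knot so the basis covers the boundary
    upper_closed <- knots[j + 1] >= knots[length(knots)]
    return(as.numeric(x >= knots[j] & (x < knots[j + 1] ||
                                         (upper_closed && x <= knots[j + 1]))))
  }
  d1 <- knots[j + degree] - knots[j]
  d2 <- knots[j + degree + 1] - knots[j + 1]
  a <- if (d1 > 0) (x - knots[j]) / d1 * cdb_one(x, knots, j, degree - 1) else 0
  b <- if (d2 > 0) (knots[j + degree + 1] - x) / d2 *
    cdb_one(x, knots, j + 1, degree - 1) else 0
  a + b
}

cdb_basis <- function(x, knots_full, degree) {
  nb <- length(knots_full) - degree - 1L
  sapply(seq_len(nb), function(j)
    vapply(x, cdb_one, 0, knots = knots_full, j = j, degree = degree))
}

# Row-by-row Bernoulli log likelihood.
bernoulli_loglik_brute <- function(beta, Z, y) {
  total <- 0
  for (r in seq_len(nrow(Z))) {
    h <- 1 / (1 + exp(-sum(Z[r, ] * beta)))
    total <- total + if (y[r] == 1) log(h) else log(1 - h)
  }
  total
}

# A small long-format cohort written to a temp file and read back.
toy_cohort_file <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

patient9_path <- function() {
  system.file("extdata", "patient9.csv", package = "dtsgam")
}

patient5_path <- function() {
  system.file("extdata", "patient5.csv", package = "dtsgam")
}

# Small simulated person-period table for fitting tests.
small_pp <- function(n = 60, seed = 7, ...) {
  cohort <- simulate_cohort(cohort_config(n_subjects = n, seed = seed, ...))
  expand_person_period(cohort$subjects)
}
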