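#' Test a time-dependent competing-event covariate by deviance reduction
#'
#' Fits the base model and the base model plus a linear, unpenalized binary
#' covariate coding the competing event (0 before it, 1 at its interval;
#' see [encode_transplant()]), at the same smoothing parameters, and tests
#' the deviance reduction against a chi-square with the difference in
#' effective degrees of freedom (fractional df allowed). Competing events
#' are otherwise treated as censoring: those subjects never contribute an
#' event row.
#'
#' @param data a `person_period` table containing the competing-event
#'   column.
#' @param terms base-model term list.
#' @param lambda smoothing parameters for the base model's smooth terms.
#' @param column name of the competing-event covariate.
#' @return A list of class `dtsgam_lr` (see [lr_test()]) with the two fits
#'   attached as `fit_base` and `fit_extended`.
#' @export
transplant_lr_test <- function(data, terms, lambda, column = "transplant") {
  if (inherits(terms, "term_spec")) terms <- list(terms)
  if (!column %in% names(data))
    stop("column '", column, "' not found; run encode_transplant() first")
  if (all(data[[column]] == 0))
    stop("no subject experienced the competing event; the test is undefined")
  fit_base <- dtsgam(data, terms, lambda = lambda)
  fit_ext <- dtsgam(data, c(terms, list(linear_term(column))),
                    lambda = c(fit_base$lambda, 0))
  out <- lr_test(fit_base, fit_ext)
  out$fit_base <- fit_base
  out$fit_extended <- fit_ext
  out
}
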