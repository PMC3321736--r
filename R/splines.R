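#' Specify a penalized smooth term
#'
#' Declares that a covariate (or the interval midpoint, via the reserved
#' name `"time"` mapped to the `midpoint` column) enters the hazard's linear
#' predictor through a B-spline smooth with a squared-second-derivative
#' roughness penalty. The basis has `n_interior + degree + 1` functions
#' before the sum-to-zero centering constraint removes one.
#'
#' @param var covariate name; `"time"` refers to the interval midpoint.
#' @param n_interior number of interior knots (default 10), placed at
#'   equally spaced quantiles of the observed values.
#' @param degree spline degree; cubic (3) by default. The penalty requires
#'   `degree >= 2`.
#' @return A `term_spec` of kind `"smooth"`.
#' @seealso [linear_term()], [build_design()]
#' @export
smooth_term <- function(var, n_interior = 10, degree = 3) {
  stopifnot(is.character(var), length(var) == 1L,
            n_interior >= 1, degree >= 1)
  structure(list(kind = "smooth", var = var,
                 n_interior = as.integer(n_interior),
                 degree = as.integer(degree)),
            class = "term_spec")
}

#' Specify an unpenalized linear term
#'
#' @param var covariate name (or `"time"` for the interval midpoint).
#' @return A `term_spec` of kind `"linear"`, contributing one raw column.
#' @export
linear_term <- function(var) {
  stopifnot(is.character(var), length(var) == 1L)
  structure(list(kind = "linear", var = var), class = "term_spec")
}

#' @export
print.term_spec <- function(x, ...) {
  if (x$kind == "smooth")
    cat(sprintf("s(%s): degree %d, %d interior knots\n", x$var, x$degree,
                x$n_interior))
  else cat(sprintf("%s (linear)\n", x$var))
  invisible(x)
}

term_label <- function(spec) {
  if (spec$kind == "smooth") paste0("s(", spec$var, ")") else spec$var
}

#' Place B-spline knots from observed covariate values
#'
#' Interior knots go at equally spaced quantiles of the observed values
#' (robust to skewed covariates such as bilirubin); boundary knots sit at
#' the data minimum and maximum and are replicated `degree + 1` times so the
#' basis spans the full data range.
#'
#' @param values numeric sample of the covariate.
#' @param n_interior number of interior knots.
#' @param degree spline degree.
#' @return A list with `interior`, `boundary` (length 2) and `full` (the
#'   replicated knot vector as used by the basis evaluator).
#' @export
place_knots <- function(values, n_interior, degree = 3) {
  values <- values[is.finite(values)]
  ux <- unique(values)
  if (length(ux) < n_interior + 2L)
    stop("too few distinct values (", length(ux), ") for ", n_interior,
         " interior knots; reduce the knot count")
  probs <- seq_len(n_interior) / (n_interior + 1)
  interior <- unname(stats::quantile(values, probs = probs, type = 7))
  boundary <- range(values)
  if (any(interior <= boundary[1]) || any(interior >= boundary[2]) ||
      anyDuplicated(interior))
    stop("degenerate interior knots (ties in the covariate quantiles); ",
         "reduce the knot count")
  list(interior = interior, boundary = boundary,
       full = c(rep(boundary[1], degree + 1L), interior,
                rep(boundary[2], degree + 1L)))
}

#' Evaluate a B-spline basis
#'
#' Evaluates the `n_interior + degree + 1` B-spline basis functions (or a
#' derivative) on the replicated knot vector of [place_knots()]. Values
#' outside the boundary knots are clamped to the boundary with a warning,
#' unless `clamp = FALSE`, in which case they are an error.
#'
#' @param x numeric vector of evaluation points.
#' @param knots a knot list from [place_knots()].
#' @param degree spline degree.
#' @param deriv derivative order (0 = function values).
#' @param clamp clamp out-of-range `x` to the boundary knots?
#' @return A `length(x)` by `n_interior + degree + 1` matrix. For
#'   `deriv = 0` each row is nonnegative and sums to one.
#' @export
bspline_basis <- function(x, knots, degree = 3, deriv = 0, clamp = TRUE) {
  lo <- knots$boundary[1]; hi <- knots$boundary[2]
  out_of_range <- x < lo | x > hi
  if (any(out_of_range)) {
    if (!clamp)
      stop("values outside the boundary knots with clamping disabled")
    warning(sum(out_of_range), " value(s) outside [", signif(lo, 6), ", ",
            signif(hi, 6), "] clamped to the boundary knots")
    x <- pmin(pmax(x, lo), hi)
  }
  splines::splineDesign(knots$full, x, ord = degree + 1L,
                        derivs = rep(deriv, length(x)))
}

#' Roughness penalty matrix for a smooth term
#'
#' Computes the matrix `S` with entries `S[j, k] = integral of
#' b_j''(t) b_k''(t) dt` over the knot span, so that for spline coefficients
#' `beta` the quadratic form `t(beta) %*% S %*% beta` equals the integrated
#' squared second derivative of the fitted smooth. The integral is exact:
#' the second derivatives are piecewise polynomials of degree `degree - 2`,
#' and Gauss-Legendre quadrature of sufficient order is applied per knot
#' span.
#'
#' The null space of `S` contains exactly the coefficient vectors
#' representing constant and linear functions.
#'
#' @param knots a knot list from [place_knots()].
#' @param degree spline degree, at least 2.
#' @return A symmetric positive semidefinite matrix of dimension
#'   `n_interior + degree + 1`.
#' @export
penalty_matrix <- function(knots, degree = 3) {
  if (degree < 2)
    stop("second-derivative penalty requires degree >= 2")
  kv <- knots$full
  nb <- length(kv) - degree - 1L              # number of basis functions
  spans <- unique(kv)
  gl_n <- max(1L, degree - 1L)                # exact for degree 2*(degree-2)
  gl <- gauss_legendre(gl_n)
  S <- matrix(0, nb, nb)
  for (i in seq_len(length(spans) - 1L)) {
    a <- spans[i]; b <- spans[i + 1L]
    if (b <= a) next
    t_nodes <- (b - a) / 2 * gl$nodes + (a + b) / 2
    w <- (b - a) / 2 * gl$weights
    B2 <- splines::splineDesign(kv, t_nodes, ord = degree + 1L,
                                derivs = rep(2L, length(t_nodes)))
    S <- S + crossprod(B2 * sqrt(w))
  }
  (S + t(S)) / 2
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method (symmetric tridiagonal Jacobi matrix).
gauss_legendre <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 2))
  k <- seq_len(n - 1L)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- beta
  J[cbind(k + 1L, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * (e$vectors[1, ord])^2)
}

# Resolve a term spec against training data: knots, raw penalty, and the
# sum-to-zero constraint transform Q (absorbing 1'Xb = 0 by a Householder
# null-space basis), all frozen for later prediction.
resolve_term <- function(spec, x) {
  if (spec$kind == "linear") {
    spec$ncol <- 1L
    return(spec)
  }
  knots <- place_knots(x, spec$n_interior, spec$degree)
  X <- bspline_basis(x, knots, spec$degree)
  C <- colSums(X)
  Q <- qr.Q(qr(matrix(C, ncol = 1L)), complete = TRUE)[, -1L, drop = FALSE]
  S <- penalty_matrix(knots, spec$degree)
  spec$knots <- knots
  spec$Q <- Q
  spec$S <- crossprod(Q, S %*% Q)   # penalty in constrained coordinates
  spec$ncol <- ncol(Q)
  spec
}

term_values <- function(spec, data) {
  var <- if (spec$var == "time") "midpoint" else spec$var
  if (!var %in% names(data))
    stop("covariate '", var, "' not found in the data")
  data[[var]]
}

term_columns <- function(spec, x) {
  if (spec$kind == "linear") return(matrix(x, ncol = 1L))
  bspline_basis(x, spec$knots, spec$degree) %*% spec$Q
}

#' Build the stacked design matrix for a person-period table
#'
#' Assembles the model matrix `Z`: a leading intercept column followed by
#' one column block per term. Smooth blocks are B-spline bases under a
#' sum-to-zero centering constraint (absorbed into the basis, removing one
#' column) so the model with a free intercept is identifiable; linear terms
#' contribute one raw column. Each smooth block's penalty matrix is
#' transformed into the same constrained coordinates.
#'
#' @param data a `person_period` data frame (or any data frame holding the
#'   term covariates; `"time"` terms use the `midpoint` column).
#' @param terms list of [smooth_term()] / [linear_term()] specs.
#' @return A list of class `dtsgam_design` with elements `Z` (the model
#'   matrix), `terms` (resolved specs with frozen knots and constraint
#'   transforms), `blocks` (column indices per term), and `penalties`
#'   (constrained penalty matrix per smooth term, `NULL` for linear terms).
#' @export
build_design <- function(data, terms) {
  if (inherits(terms, "term_spec")) terms <- list(terms)
  stopifnot(all(vapply(terms, inherits, TRUE, "term_spec")))
  resolved <- lapply(terms, function(sp) resolve_term(sp, term_values(sp, data)))
  cols <- lapply(resolved, function(sp) term_columns(sp, term_values(sp, data)))
  Z <- cbind(`(Intercept)` = rep(1, nrow(data)), do.call(cbind, cols))
  widths <- vapply(resolved, function(sp) sp$ncol, 0L)
  if (length(widths)) {
    ends <- 1L + cumsum(widths)
    blocks <- Map(seq, ends - widths + 1L, ends)
    names(blocks) <- vapply(resolved, term_label, "")
  } else blocks <- list()
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z))
    warning("design matrix is rank deficient after centering (rank ",
            qrz$rank, " < ", ncol(Z), " columns)")
  structure(list(Z = Z, terms = resolved, blocks = blocks,
                 penalties = lapply(resolved, function(sp) sp$S)),
            class = "dtsgam_design")
}

# Evaluate the design for new rows using the frozen knots/constraints.
design_rows <- function(design, newdata) {
  cols <- lapply(design$terms, function(sp)
    term_columns(sp, term_values(sp, newdata)))
  cbind(rep(1, nrow(newdata)), do.call(cbind, cols))
}
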