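---
title: "Penalized additive models for discrete-time survival with time-dependent covariates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized additive models for discrete-time survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtsgam)
```

## The model

`dtsgam` targets cohorts in which patients return to the clinic repeatedly
and their prognostic markers are re-measured at every visit — the canonical
example being sequential follow-up of primary biliary cirrhosis, with
bilirubin, prothrombin time and age evolving over a decade of visits until
death, censoring, or liver transplantation. Proportional-hazards machinery
is awkward here: with time-dependent covariates the survivor function is no
longer a power of a baseline survivor function, and short-term forecasts
("will this patient survive the next six months?") need the hazard as an
explicit function of the *current* marker values.

The package instead discretizes time at the visits themselves. Subject $d$
with $l_d$ visits contributes one Bernoulli trial per visit interval
$[t_l, t_{l+1})$, with response $\delta_l = 1$ only if the subject died in
that interval. The discrete hazard $h_l$ — the conditional probability of
death in interval $l$ given survival to its start — is modeled on the logit
scale as an additive combination of smooth covariate effects evaluated at
the interval's covariate values, with the interval midpoint $a_l$ available
as a time effect:

$$\operatorname{logit} h_l = \beta_0 + s_0(a_l) + s_1(x_{l1}) + \cdots + s_I(x_{lI}).$$

Each smooth is a cubic B-spline expansion (10 interior knots by default,
placed at quantiles of the observed values; boundary knots at the data
range). The log likelihood of the expanded person-period table is the
ordinary Bernoulli log likelihood — the per-subject product over intervals
is algebraically identical to the row product — and estimation maximizes
the penalized version

$$\ell(\beta) - \tfrac12 \sum_i \lambda_i \int \{s_i''(t)\}^2\,dt,$$

so each $\lambda_i \ge 0$ trades fidelity against curvature. The penalty
subtracts from the log likelihood; the null space of each term's penalty is
the constant-plus-linear family, so $\lambda_i \to \infty$ shrinks a smooth
to a straight line, never to zero effect. The deviance is $-2\ell(\hat\beta)$
(the saturated model for ungrouped binary data attains log likelihood 0),
and model complexity is measured by the effective degrees of freedom
$\mathrm{edf} = \operatorname{tr}\{(Z'WZ + S_\lambda)^{-1} Z'WZ\}$ at
convergence, which reproduces the usual residual-df arithmetic
$N - \mathrm{edf}$.

### Identifiability and numerics

A free intercept plus an unconstrained B-spline block is rank deficient
(each basis row sums to one), so every smooth block is centered by a
sum-to-zero constraint absorbed into the basis: one column is removed by a
Householder null-space rotation of the constraint $\mathbf 1' X \beta = 0$,
and the penalty matrix is rotated into the same coordinates. The penalty
itself is computed exactly: second derivatives of degree-$p$ B-splines are
piecewise polynomials of degree $p-2$, so Gauss–Legendre quadrature with
$p-1$ nodes per knot span integrates their products without error.

Fitting uses penalized iteratively reweighted least squares (Fisher
scoring) with step halving on the penalized objective, relative tolerance
$10^{-8}$, at most 200 iterations, and a tiny ridge ($10^{-10}$, applied
only when the penalized normal equations are computationally singular, and
flagged). The penalized objective is non-decreasing across iterations by
construction. Degenerate situations are signaled, not silently absorbed:
quasi-separation (fitted hazards pinned at 0/1 with a large linear
predictor), rank deficiency after centering, covariate values outside the
training range (clamped to the boundary knots with a warning).

## Choosing the smoothing parameters

Ordinary leave-one-*row*-out cross-validation is the wrong resolution for
person-period data: a subject's rows share their covariate path, so deleting
single rows leaks information across folds. The package's criterion deletes
one *subject* at a time — all of a patient's rows together — refits, and
scores the held-out subject's Bernoulli log likelihood under the refitted
hazards. The score is reported as $-2$ times the summed held-out log
likelihood so it lives on the same scale as the deviance and AIC
($\mathrm{Dev} + 2\,\mathrm{edf}$), and it decomposes additively over
subjects. Selection is by exhaustive search over a log-spaced grid
(default $10^{-4}..10^2$), with ties broken toward the larger, smoother
$\lambda$; a grid rather than a continuous optimizer keeps the selection
reproducible and matches the coarse resolution at which the criterion
distinguishes candidates in data of this size. The deviance-based
GCV score $N\,\mathrm{Dev}/(N - \mathrm{edf})^2$ is provided as the
classical row-level comparator only. Each fold is warm-started from the
full-data fit, which makes the $n$ refits cheap (a few Newton steps each).

Spline-versus-linear comparisons use the deviance difference between
nested penalized fits referred to a chi-square whose df is the edf
difference; fractional df use the continuous (gamma) chi-square form.
Per-term Wald screens (coefficient block against its penalized covariance,
with the term's edf as reference df) are provided for covariate screening
and documented as approximate.

## Goodness of fit by bootstrap

For ungrouped binary responses the deviance is not even approximately
chi-square, so the package estimates a critical value by resampling:
$B$ bootstrap cohorts are drawn by sampling *subjects* with replacement
(row resampling would destroy the within-patient history structure), the
model is refitted to each with the same $\lambda$ and frozen basis, and the
$j$th order statistic of the replicate deviances estimates the quantile of
order $j/(B+1)$; the decision compares the observed deviance with the
$100(1-\alpha)$ percentile (rank $j = \operatorname{round}\{(1-\alpha)(B+1)\}$).

Users should understand what this decision can and cannot do. The case
bootstrap centers the replicate deviances near the observed one, so when
the model is correct the observed deviance sits in the middle of the
replicate distribution (empirically near its 55th percentile in our
simulations) and the rejection rate is far below the nominal $\alpha$: the
test is a *gross misfit screen*, not a calibrated size-$\alpha$ test. A
`type = "parametric"` option simulates replicate responses from the fitted
hazards at the observed rows instead; this is the textbook GLM reference,
but in the sequential setting it remains conservative because death
truncates follow-up — event count and row count are negatively coupled in
real cohorts, so the sampling spread of the observed deviance is smaller
than the fixed-row Bernoulli reference (we measure an across-cohort sd of
roughly two thirds of the within-bootstrap sd at 100 subjects). Both
variants are deterministic given the seed, via per-replicate substreams.

## Prediction

Fitted hazards convert to survival by the discrete product
$S(t_l) = \prod_{i \le l} (1 - h_i)$, and short-term conditional survival by
$\Pr(t, \Delta t) = S(t + \Delta t)/S(t)$. On the interval grid this is
implemented as the product of $1 - h_i$ over intervals whose *start* lies
in $[t, t + \Delta t)$, a convention chosen because it makes the window
algebra exact: $\Pr(t, \Delta_1 + \Delta_2) =
\Pr(t, \Delta_1)\Pr(t + \Delta_1, \Delta_2)$ holds identically for any
split, and a whole-interval window at constant hazard gives $1 - h$. When a
six-month window (182.5 days by default) extends past a subject's observed
follow-up, the grid is extended with intervals of the subject's last
observed length and the last visit's covariate values are carried forward —
the minimal extrapolation assumption, stated rather than hidden. Group
summaries average the per-visit conditional survival over the subjects
still under observation at each visit index, separately for subjects who
eventually died versus were censored, and per-visit quantile tables support
box-plot style displays.

## Competing risk as a covariate

Liver transplantation removes a patient from observation without the death
event; the package treats it as censoring *plus*, optionally, a
time-dependent binary covariate coded 0 before and 1 at the transplant
visit. The covariate enters linearly and unpenalized (it is binary), and
its contribution is tested by deviance reduction between the base and
extended fits at matched $\lambda$, on the (typically fractional) edf
difference. Because a transplant row is structurally a non-event, the
information in the test comes from transplanted patients' predicted hazards
at their final visits: transplantation that targets high-risk patients
produces a strongly negative coefficient and a large deviance reduction.

## The cohort simulator

`simulate_cohort()` generates visit-structured cohorts that follow the
model exactly, so every estimation component can be validated against
known truth. Its defaults emulate the scale of sequential PBC follow-up:
312 subjects with visits at six months, twelve months, then yearly with
±30-day jitter; administrative end of follow-up uniform between 3 and 12
years; per-interval loss to follow-up 3%; age advancing deterministically;
prothrombin time (seconds) and log-bilirubin following random walks with
mild upward drift between visits (covariates are piecewise constant within
intervals, matching the model's assumption); and a per-interval death
probability `plogis(-2.9 + 0.035 (age - 50) + 0.30 (pro - 10.7) +
1.2 (log bili - log 3))`. The bilirubin effect is deliberately log-shaped —
steep at low values, saturating at high values — so spline-versus-linear
comparisons have a genuinely nonlinear truth to detect; the baseline and
dispersions were set so that a default cohort produces roughly 1,800–1,900
person-period rows with roughly 45% deaths, the shape of the real
sequential data. An optional transplantation rule removes high-bilirubin
subjects with a configured probability.

What the simulator does *not* emulate: the real joint distribution of PBC
markers (correlations between bilirubin and prothrombin time, albumin,
edema, treatment effects), informative visit timing (sicker patients
returning sooner), measurement error in covariates, or interval-censored
event times within a visit interval. Passing recovery tests on simulated
cohorts therefore demonstrates the estimation machinery is correct under
the model's own assumptions, not that the model is adequate for any given
real cohort — that is what the goodness-of-fit and cross-validation tools
are for.

## Problem sizes and reproducibility

The validation suite and the acceptance script run the full workflow at
the sizes a desk analysis would use: 312-subject cohorts (≈1,900 rows) for
fitting and selection, 300 subjects for the nonlinearity-detection and
competing-risk checks, 100-cohort Monte-Carlo loops at 100 subjects and
B = 99 for bootstrap calibration measurements. A single penalized fit on
1,900 rows with ~30 coefficients takes ~30 ms; a full leave-one-subject-out
CV evaluation ~1 s; grid selection over two smooth terms a couple of
minutes. All randomness flows from a single integer seed through
deterministic per-replicate substreams.

## Known limitations

- Interval boundaries are reconstructed from consecutive visit days; the
  final interval ends at the recorded end of follow-up. Events are located
  only to an interval, never within one.
- One terminal event per subject; recurrent events are out of scope.
- Smooths are univariate; no tensor-product interactions.
- No pointwise confidence bands for the estimated smooths.
- The bootstrap goodness-of-fit decision is conservative under a correct
  model (see above); treat "no rejection" as absence of gross misfit.
- The subdistribution (cumulative-incidence) formulation of competing
  risks is intentionally not implemented; transplantation is handled only
  through censoring plus the indicator covariate.
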