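---
title: "Score-based DIF tests for ordinal factor models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-based DIF tests for ordinal factor models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ofadif` estimates multidimensional graded response models in their ordinal
factor analysis form. Each of `p` items takes ordered categories
`1..l_j`; a continuous latent response `Y*_j = lambda_j' xi + eps_j`
underlies item `j`, with factor scores `xi ~ N(0, Psi)` and the threshold
relation `Y_j = k` iff `tau_{j,k-1} < Y*_j <= tau_{j,k}`. The cumulative
category probability is the probit of the (standardized) threshold minus
the weighted latent composite.

The package uses the **delta parameterization** throughout: every latent
response has total variance 1, so the residual variance is derived as
`1 - lambda_j' Psi lambda_j`, free loadings live inside the unit ball, and
the model-implied second-order moments are correlations. This matches the
estimation target — a polychoric *correlation* matrix — and makes the
implied moment vector `kappa(theta) = (tau(theta), sigma*(theta))` of
length `p* = p(l-1) + p(p-1)/2` fully determined by `theta`.

Identification follows the standard convention: per factor, either the
latent variance is fixed to 1 with all loadings free (`std_lv = TRUE`, the
default and the shape used in all simulations here), or the first loading
is fixed to 1 with the variance free. Structures such as a model with all
loadings fixed to 1 and free latent covariances are expressible through
`grm_spec()` / `parse_model_syntax()`.

## Estimation

Estimation is the two-stage limited-information route:

1. **Thresholds** are probit-inverted cumulative proportions, the exact ML
   solution of the saturated univariate model. Every category must be
   observed, otherwise the stage errors (naming item and category).
2. **Polychoric correlations** maximize the bivariate-normal
   contingency-table likelihood pair by pair with the thresholds held
   fixed (the two-step estimator). Rectangle probabilities come from a
   vectorized Gauss–Legendre bivariate-normal CDF (absolute accuracy about
   1e-14 for |rho| <= 0.925, exact TVPACK evaluation beyond); the search is
   restricted to (-0.999, 0.999) and boundary solutions are clipped with a
   warning.
3. **The weight matrix `W`** estimates `n` times the asymptotic covariance
   of the stacked moments via per-case influence functions of the
   two-stage estimator. Threshold contributions are scaled probit
   estimating functions `(1{y<=k} - Phi(tau)) / phi(tau)`; correlation
   contributions are pairwise likelihood scores corrected for the sampling
   error of the thresholds they condition on (the block-triangular
   construction, with the cross-derivative block obtained by numerically
   differentiating the analytic per-cell score tables). `W` must be
   positive definite; a singular `W` is an error that suggests the DWLS
   option.
4. **WLS** minimizes `F(theta) = [k_hat - k(theta)]' W^-1 [k_hat -
   k(theta)]` with the analytic gradient `-2 [k_hat - k(theta)]' W^-1
   Delta`, where the Jacobian `Delta` is analytic (identity rows for
   thresholds, chain-rule rows for the correlations) and cross-checked
   against finite differences in the test suite.

Numerical choices: BFGS over an unconstrained reparameterization (first
threshold plus log-gaps per item, so threshold order holds by
construction; log latent variances), relative function tolerance 1e-12
with one polish restart, convergence declared when the gradient max-norm
falls below 1e-5. Free loadings start at 0.7, free latent covariances at
0, thresholds at their first-stage estimates. Free latent variances start
at 0.5 rather than 1: with a first loading fixed at 1, a unit variance
would start exactly on the Heywood boundary of the delta
parameterization. A quadratic barrier keeps item communalities below 0.98
and latent correlations inside the unit ball during the search; an
inadmissible (Heywood) solution at the optimum is an error, and the
replication harness records such fits as failures rather than crashing.
`estimator = "dwls"` uses only the diagonal of `W` inside the fit while
keeping the full `W` for scores and tests.

## Approximated scores

The WLS objective has no casewise decomposition, so the package computes
the approximated per-person score contributions

```
psi_i = Delta' W^-1 [ (ind_i - mean ind) ; (s_i - mean s) ]
```

where `ind_i` stacks the category-exceedance indicators `1{y_ij > k}` in
threshold order and `s_i` stacks the products of mean-centred **raw
observed categories** for item pairs in correlation order. The asymmetry —
indicators in the first block, raw categories in the second — is
deliberate and follows the estimating-equation construction the
approximation mimics. Columns sum to zero by algebraic identity,
independent of the parameter value, which is exactly the M-estimator
condition the fluctuation tests build on. Scores are not rescaled by `n`;
all scaling sits in the cumulative score process. The approximation is
derived under near-perfect fit of the structured model; its behaviour
under gross misspecification is not characterized.

## Fluctuation tests

`score_process()` orders persons by a covariate (stable sort, ties in
original order), cumulates the scores and decorrelates them with the
inverse symmetric square root of the outer-product-of-gradients estimate
`B = (1/n) sum psi_i psi_i'`. Under parameter stability each of the `q`
decorrelated coordinate processes converges to an independent Brownian
bridge. Six functionals are implemented:

| statistic | covariate | p-value route |
|---|---|---|
| DM (double maximum) | metric | closed form, sup-bridge series to the `q`-th power |
| CvM (Cramér–von Mises) | metric | simulated bridge paths (cached) |
| maxLM | metric | simulated bridge paths, window `H/n` in `[0.1, 0.9]` |
| LMuo | categorical | chi-square with `q (C-1)` df |
| WDMo | ordinal | joint Gaussian law of the bridge at the level boundaries (numeric rectangle, `q`-th power) |
| maxLMo | ordinal | simulated bridge values at the boundaries |

The 10% trimming window for maxLM is an implementation default (the
source literature tabulates various windows). Simulated null tables use
5000 bridge paths on a 1000-point grid (CvM, maxLM) and 20000 boundary
draws (maxLMo), with fixed internal seeds per configuration so p-values
are deterministic; tables are cached per `(statistic, q, window)` and, for
maxLMo, per boundary set snapped to a 0.05 grid — the statistic itself
always uses the exact observed boundaries. The grid snap changes null
quantiles by well under the Monte-Carlo resolution of the tables but lets
a whole replication study reuse one table.

## What the simulator emulates

`dif_scenario()` + `simulate_dif_study()` define the study conditions
of the power experiments: a unidimensional 5-item model or a
multidimensional model with three correlated factors and three items each
(the three-items-per-factor assignment and factor correlations of 0.5
are design choices of this package), `k` thresholds per item in
{1, 2, 4, 6}, total sample `n` split into focal and reference halves, and
three covariates carrying the same group signal: `Znum` (reference half
uniform on 1..100, focal on 101..200), `Zord` and `Zcat` (reference on
levels 1–2, focal on levels 3–5, so the group boundary coincides with a
level boundary). The null mode simulates one group and assigns all
covariates at random.

Parameters are drawn on the IRT (probit) scale, where discriminations are
unbounded, and converted to the delta scale by `lambda = a / sqrt(a' Psi
a + 1)`, `tau* = tau / sqrt(a' Psi a + 1)`; this keeps the documented
default discrimination range U(0.6, 1.1) admissible. Thresholds sit on
the equal-probability grid `qnorm(k/l)` with U(-0.3, 0.3) jitter and a
minimum spacing of 0.1 so no category is squeezed to negligible mass;
datasets that still miss a category are redrawn (up to 20 times, then an
error that the harness logs as a failed replication).

Focal-group shifts are U(0.3, 0.6) in magnitude. Threshold shifts use
**one sign per item** (magnitudes per threshold): a coherent difficulty
shift. With independent signs per threshold the shifts partially cancel
in the expected item score and the threshold-DIF effect size collapses
below the loading-DIF effect size, inverting the qualitative pattern the
effect-size analysis reports; with coherent shifts the loading-only NCDIF
is about 0.5–0.7 of the threshold-only NCDIF across `k`, as expected.
Loading shifts are per-loading with random sign, truncated below at 0.1.
In the all-parameter scenario the multidimensional factor correlations
also shift by U(0.1, 0.3), redrawn until positive definite. All ranges
are arguments, so externally archived values can be substituted.

What the generator does **not** emulate: impact (group differences in the
latent distribution), non-normal latent variables, missing data, and
real-item content effects. Passing tests therefore certify the estimator
and test machinery under the stated sampling model, not robustness to
those violations.

NCDIF effect sizes follow the expected-score construction: `S(xi, theta)
= sum_k (k-1) P(Y_j = k | xi)` and `NCDIF_j = mean over focal xi of [S_F -
S_R]^2`.

## The replication harness and problem sizes

`run_study()` executes simulate → fit → score → test over a cell grid,
with per-replication seeds `master + 100000 * cell + rep`, so results are
reproducible bit for bit and independent of execution order; failed fits
are excluded from the denominator and counted. Each replication applies
DM, CvM and maxLM to `Znum`, WDMo and maxLMo to `Zord`, and LMuo to
`Zcat`, mirroring the statistic-to-covariate pairing of the study design.

The shipped study runs at desk scale: a full-scale version of this
design would use on the order of 1000 replications per cell across a
36-cell grid per model, while `scripts/acceptance.R` uses 50–500
replications per cell over representative grids (documented inline),
sized so the whole study runs on one CPU in minutes. Binomial Monte-Carlo standard
errors are reported alongside every rejection rate.

Two empirical notes from this reproduction, both visible in the
acceptance output rather than asserted blindly: the Type I error of all
six statistics stays in the nominal 3–6% band at the scales above; and
under loading-only DIF with the documented default shift ranges, the
max-type statistics (DM, WDMo) sit noticeably below the sum-type
statistics (CvM, maxLM, maxLMo), so the minimum-across-statistics power
in that scenario is sensitive to the unpublished shift magnitudes of the
original study.

## Known limitations

- Listwise-complete integer responses only; no missing-data handling.
- Single-group models without impact; anchor-item multiple-group testing
  is out of scope.
- The probit link only (no logit variant).
- Standard errors and fit indices for `theta` are not computed; the fit
  object carries what the score tests need.
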