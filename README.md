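# ofadif

Score-based parameter instability tests for ordinal factor models —
graded response models (GRMs) estimated by the limited-information route
of ordinal (confirmatory) factor analysis.

## The problem

Item response data — questionnaire items with a handful of ordered
categories — are routinely modelled with multidimensional GRMs. A core
validity question is **differential item functioning (DIF)**: do item
parameters drift with person covariates such as age, education or group
membership, given the latent trait? Score-based fluctuation tests answer
this without pre-specifying subgroups: they order per-person model score
contributions along a covariate, cumulate and decorrelate them, and
reject stability when the resulting process fluctuates more than a
Brownian bridge allows. Those tests need casewise scores — which the
weighted least squares (WLS) estimator of ordinal factor analysis does
not naturally provide, because its objective is a quadratic form in
aggregated moments, not a sum over persons.

`ofadif` implements the full chain for users of ordinal factor models:

1. **Estimation.** Thresholds `tau_jk = Phi^-1(P(Y_j <= k))`, Olsson
   two-step polychoric correlations, the influence-function estimate of
   the asymptotic covariance `W` of the stacked moments `kappa_hat`, and
   WLS estimation of `theta` (thresholds, loadings, latent covariances)
   by minimizing `F(theta) = [kappa_hat - kappa(theta)]' W^-1 [kappa_hat -
   kappa(theta)]` with an analytic Jacobian (delta parameterization).
2. **Approximated scores.** Per-person score contributions
   `psi_i = Delta' W^-1 [(ind_i - mean ind); (s_i - mean s)]`, with
   category-exceedance indicators in the threshold block and raw
   category cross products in the correlation block; columns sum to zero
   by construction.
3. **Instability tests.** The cumulative score process
   `CSP(H) = B^-1/2 n^-1/2 sum_{h<=H} psi_(h|Z)` and the six statistics
   DM, CvM, maxLM (metric covariates), WDMo, maxLMo (ordinal), LMuo
   (categorical), with closed-form, chi-square or Brownian-bridge
   simulated p-values.
4. **Simulation & harness.** A GRM simulator with focal/reference DIF
   scenarios, NCDIF effect sizes, and a replication harness that
   tabulates Type I error and power.

## Worked example

```r
library(ofadif)

# a 5-item, 3-category unidimensional model
spec <- grm_spec(list(F1 = paste0("y", 1:5)), n_cat = 3)

# simulate a study in which item 1's thresholds differ between the
# covariate-aligned focal and reference halves
scn <- dif_scenario("unidimensional", k = 2, n = 1000,
                    scenario = "thresholds_subset", seed = 42)
dat <- simulate_dif_study(scn, seed = 43)

fit <- fit_ofa(dat, spec)
glance(fit)
#> # A tibble: 1 × 7
#>   objective converged n_iter gradient_norm     n n_free estimator
#>       <dbl> <lgl>      <int>         <dbl> <int>  <int> <chr>
#> 1   0.00216 TRUE          31       2.11e-9  1000     15 wls

dif_test(fit, dat$Znum, type = "metric")
#> # A tibble: 3 × 7
#>   covariate type   statistic value     p_value method      n_params
#>   <chr>     <chr>  <chr>     <dbl>       <dbl> <chr>          <int>
#> 1 dat$Znum  metric DM         2.96 0.000000776 closed_form       15
#> 2 dat$Znum  metric CvM        4.39 0.0066      simulated         15
#> 3 dat$Znum  metric maxLM     46.1  0.0022      simulated         15
```

The small p-values flag the injected instability; `tidy(fit)` lists the
parameter estimates, `approx_scores(fit)` returns the n × |theta| score
matrix, and `autoplot(score_process(approx_scores(fit), dat$Znum))` shows
the peaked fluctuation process. A Type I error / power table is one
call:

```r
grid <- study_grid("unidimensional", k = 2, n = 1000,
                   scenario = "null", n_reps = 200)
run_study(grid, master_seed = 7)
```

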