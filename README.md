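# capform

Life-course self-regulation and mid-life capital formation: a tested R
implementation of a pre-registered small-sample analysis pipeline.

## The problem

Cohorts that measured preschool **delay of gratification** — how long a
child waits, up to a 900 s limit, for a larger reward — are now old
enough for participants to report mid-life **capital formation**: net
worth, permanent income, savings, education, forward-looking behaviors,
and so on. Testing whether early self-regulation predicts these outcomes
runs into three problems at once: the preschool task was administered in
~21 experimental conditions of wildly unequal size with right-censored
wait times; the analysis sample is small (~113 respondents, 103–113 per
outcome); and two predictors × 11 outcomes invite multiple-testing false
positives while family-wise corrections destroy power.

`capform` implements the pre-registered solution end to end, for anyone
who wants to reuse, audit, or stress-test it:

* **Rank-normalized delay (RND).** A random-effects tobit model of log
  wait time,

  $$y^*_{gi} = \alpha + \beta_1\,\mathrm{age}_{gi} +
    \beta_2\,\mathrm{male}_{gi} + \eta_g + \varepsilon_{gi}, \qquad
    \eta_g \sim N(0,\sigma_\eta^2),\ \varepsilon_{gi} \sim
    N(0,\sigma_\varepsilon^2),$$

  estimated by maximum likelihood with adaptive Gauss–Hermite
  quadrature (`fit_tobit_re()`), yields an empirical-Bayes expected log
  wait per condition/age/sex; each child's deviation from it (censored
  waits replaced by the simulated truncated-normal conditional
  expectation) is rank-normalized (`compute_rnd()`).
* **Composite indices.** CCQ-style item batteries at ages 17/27/37 are
  scored into six equal-weighted subscales and aggregated
  (`score_ccq()`); the composite self-regulation index RNSRI averages
  RND with the three age indices (`compute_rnsri()`); every variable
  passes through the rank-based inverse normal transform
  (`rank_inverse_normal()`).
* **Inference battery.** Per-outcome OLS with a sex control
  (`ols_assoc()`), Benjamini–Hochberg FDR at 0.1 (`bh_fdr()`), a
  permutation-calibrated joint Wald test across all 11 outcomes
  (`permutation_wald()`), and conjugate normal–normal shrinkage toward
  the elicited prior (`bayes_shrinkage()`), summarized by the average
  correlation-scale coefficient (`run_battery()`).
* **Synthetic cohort.** The real cohort is confidential, so
  `generate_cohort()` draws cohorts with the same statistical skeleton
  (censored log-normal waits at the published tobit estimates, a latent
  self-regulation factor behind items and outcomes, the published
  missingness pattern), calibrated so the estimated battery
  correlations average ≈ 0.19 for the composite index and ≈ 0.02 for
  the preschool score. The published per-outcome estimates themselves
  ship as data (`published_associations()`).

## Worked example

```r
library(capform)

spec   <- cohort_spec(seed = 1)          # 543 children, 21 conditions
cohort <- generate_cohort(spec)
fit    <- fit_tobit_re(cohort$wait_records)
fit
#> Random-effects tobit model of log wait time (censored at 900 s)
#>                               estimate    se
#> Age at delay task (months)       0.083 0.021
#> Male                            -1.036 0.239
#> Constant                         2.493 1.124
#> SD of condition random effect    0.500 0.169
#> SD of individual error           2.557 0.112
#> N = 543 (227 censored), 21 conditions, logLik = -918.20
```

Waiting rises about 8% per month of age and boys wait far less than
girls, on top of substantial condition-level heterogeneity — the reason
raw wait times cannot be compared across children directly. Building the
scores and running the battery on the 113-person survey subsample:

```r
rnd     <- compute_rnd(cohort$wait_records, fit, seed = 2)
tbl     <- build_analysis_table(cohort, rnd)
battery <- run_battery(tbl, "rnsri", seed = 3)
battery
#> Association battery for predictor: rnsri
#>              outcome estimate   se     p   n fdr_discovery posterior_mean
#>            net_worth     0.00 0.10 0.980 107         FALSE           0.03
#>     permanent_income     0.08 0.10 0.430 110         FALSE           0.09
#>  wealth_income_ratio     0.24 0.09 0.011 107          TRUE           0.22
#>   high_interest_debt     0.24 0.10 0.013 107          TRUE           0.23
#>   credit_card_misuse     0.24 0.09 0.010 111          TRUE           0.23
#>         delay_choice     0.27 0.09 0.005 110          TRUE           0.25
#>         savings_rate     0.24 0.10 0.018 103          TRUE           0.22
#>     financial_health     0.20 0.09 0.033 111          TRUE           0.19
#>      education_years     0.18 0.09 0.057 111          TRUE           0.17
#>      forward_looking     0.22 0.09 0.024 111          TRUE           0.20
#>        social_status     0.18 0.10 0.065 111          TRUE           0.17
#> mean coefficient = 0.19 (bootstrap SE 0.03); mean posterior = 0.18
#> Joint Wald test: W = 50.84, empirical p = 0.002997 (B = 1000, joint permutation)
```

Each `estimate` is on the correlation scale (both variables are
rank-normal); `posterior_mean` shrinks it toward the pre-registered
prior (mean 0.15, SD 0.2), giving effect sizes immune to
significance-selection exaggeration. On this synthetic cohort the
composite index predicts the battery (mean r = 0.19, joint p ≈ 0.003)
while the preschool score alone does not:

```r
run_battery(tbl, "rnd", prior = prior_spec(0.05, 0.2), seed = 3)
#> ...
#> mean coefficient = 0.03 (bootstrap SE 0.03)
#> Joint Wald test: W = 9.90, empirical p = 0.54 ...
```

`run_pipeline("out", seed = 1)` runs all of the above end to end,
writing delimited result tables and a JSON manifest (config, seeds,
digests, timings); `inst/cli/run_pipeline.R` wraps it for the shell.
The methods vignette (`vignettes/capform-methods.Rmd`) documents the
model, the numerical choices, and what the synthetic cohort does and
does not emulate.

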