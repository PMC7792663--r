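---
title: "Methods: self-regulation scores, censored wait-time modelling, and the small-sample inference battery"
author: "capform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-regulation scores, censored wait-time modelling, and the small-sample inference battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capform)
```

## The problem

Longitudinal cohorts that measured delay of gratification in preschool —
a child may wait, up to a censoring limit of 900 s, for a larger reward —
are now old enough for their participants to report mid-life *capital
formation*: net worth, permanent income, savings, education, and related
outcomes. Relating the two is statistically delicate for three reasons
that shape everything in this package:

1. **The preschool measure is contaminated by design variation.** The
   wait task was run in ~21 experimental conditions that differ strongly
   in how long children wait, with some condition samples as small as 3.
   Raw wait times also pile up at the 900 s limit.
2. **The analysis sample is small** (~113 survey respondents, with
   per-outcome Ns of 103–113), so per-association power is low and any
   significant estimate is exaggerated by selection ("winner's curse").
3. **Many hypotheses are tested at once** (two predictors × 11 outcomes),
   so naive p < 0.05 screening produces false positives while family-wise
   corrections destroy power.

The package implements the pre-registered answer to all three: a
condition-, age- and sex-adjusted **rank-normalized delay score (RND)**
built from a censored random-effects model; a life-course composite, the
**rank-normalized self-regulatory index (RNSRI)**; and an inference
battery of per-outcome OLS, Benjamini–Hochberg FDR at 0.1, a
permutation-calibrated joint Wald test, and conjugate Bayesian shrinkage
toward elicited priors. Because the cohort data are confidential, a
synthetic-cohort generator with the same statistical structure makes
every stage testable, and the published per-outcome estimates are shipped
as data so the battery's summary operations can be recomputed exactly.

## Rank-based inverse normal transformation

Every analysis variable is transformed to normal scores: value of rank
$r$ (average ranks for ties) among $n$ observed values maps to
$\Phi^{-1}\!\big((r - 1/2)/n\big)$. The transform preserves order, tames
outliers, and gives every variable the same marginal scale, so OLS
coefficients between transformed variables are on the correlation scale.

Numerical conventions the source analysis left open, decided here once:

* **Offset.** $(r - 1/2)/n$ is the default; Blom's
  $(r - 3/8)/(n + 1/4)$ is available via `offset = "blom"`. At $n
  \approx 113$ the largest score differs by < 0.02 and battery summaries
  are unchanged to 2 decimals.
* **Ties** receive average ranks — the symmetric, convention-free choice.
* **Sample.** The transform is applied within the set of participants
  actually observed for each variable, matching the "relative standing"
  interpretation; scores are not comparable across different analysis
  subsamples, and RND is re-normalized within the survey subsample before
  it enters the battery.

## The censored random-effects wait-time model and RND

Latent log wait times follow

$$y^*_{gi} = \alpha + \beta_1\,\mathrm{age}_{gi} + \beta_2\,\mathrm{male}_{gi}
  + \eta_g + \varepsilon_{gi},\qquad
  \eta_g \sim N(0, \sigma_\eta^2),\quad
  \varepsilon_{gi} \sim N(0, \sigma_\varepsilon^2),$$

with the observed wait $\min(e^{y^*}, 900)$ s. Conditions enter as a
random effect because several are far too small for fixed effects.
`fit_tobit_re()` maximizes the marginal likelihood in which censored
records contribute $P(y^* \ge \ln 900 \mid \eta_g)$ and uncensored
records the normal density, integrating $\eta_g$ out numerically.

**Numerics.** The integral uses adaptive Gauss–Hermite quadrature with 21
nodes by default: per condition, the mode of the (strictly concave) log
integrand is found by damped Newton iteration and the nodes are centred
and scaled there. The unit tests cross-check the quadrature against
brute-force grid integration to $10^{-7}$. Optimization runs `nlminb` on
$(\alpha, \beta_1, \beta_2, \log\sigma_\eta, \log\sigma_\varepsilon)$
from three *deterministic* perturbations of a moments-based start (the
fit is a deterministic function of the data); convergence demands the
optimizer's relative tolerance of $10^{-10}$, and standard errors come
from the observed information with the delta method for the SDs.
Degenerate inputs fail loudly: a single condition (random-effect SD not
identified), an all-censored sample (no interior optimum), or a boundary
optimum.

**Edge conventions.** Wait times recorded as 0 s are floored at 1 s
before logging (ln 0 is undefined; 1 s is below any meaningful wait).
Only each participant's first delay-task record is used — repeat
exposures mean something different — so duplicate ids keep the earliest
row with a warning.

**RND** is built in three steps: the *expected* log wait for each
participant is $\hat\alpha + \hat\beta_1\mathrm{age} +
\hat\beta_2\mathrm{male} + \hat\eta_g$ with $\hat\eta_g$ the
empirical-Bayes posterior mean of the condition effect (parameter
estimates treated as truth); the *deviation* subtracts this from the
actual log wait, where censored participants instead use the simulated
conditional expectation $E[y^* \mid y^* \ge \ln 900]$ from 10,000
truncated-normal draws (the closed inverse-Mills form is the test
oracle); and the deviations are rank-normalized. Whether the original
imputation integrated over the condition-effect posterior or plugged in
its point estimate is not documented; the default here conditions on the
point estimate, matching the "estimates as true parameters" language,
and `eta = "posterior"` exposes the alternative.

## Composite indices

`score_ccq()` turns a CCQ-style item battery (23 items at age 17, 31 at
ages 27 and 37) into an age-specific self-regulation index: reverse
negatively keyed items, average items within each of six subscales
(delay of gratification, general cognitive ability, attention, coping,
goal pursuit, concern for others), rank-normalize each subscale, average
the six with equal weight, rank-normalize again. Subscale membership is
configuration, not code: `default_ccq_subscales()` ships definitions
matching the synthetic generator's item ids, and real data supplies its
own lists.

**RNSRI** is the equal-weighted mean of RND and the three age indices,
re-rank-normalized. Multi-component constructions use one missing-data
rule throughout (`equal_weight_index()`): a participant is scored when at
least half the components are observed (at least 2 of 4 for RNSRI),
otherwise missing; complete-case behaviour is available by setting
`min_present` to the number of components. The original analysis
mentions alternative imputations without detail, so both modes are
exposed and the half rule — which reproduces the published pattern of
composite-index Ns falling a few participants below the per-outcome Ns —
is the default.

Outcome constructions follow their definitions: annual high-interest
debt is $\sum_k \mathrm{amount}_k \cdot \max(\mathrm{rate}_k - 0.06,
0)$ with bucket-midpoint rates; permanent income averages two income
years per household adult (inflation adjustment is the caller's, i.e.
the data's, responsibility); delay choice is the raw fraction of "money
later" choices over 40 questions; unfavourable outcomes (high-interest
debt, credit card misuse) are negated before rank-normalization so that
larger always means better.

## The inference battery

For one predictor and each outcome, `ols_assoc()` regresses the
rank-normalized outcome on the predictor and a sex control (the
savings-rate equation also controls for permanent income), on that
outcome's complete cases, with conventional SEs and $t_{N-k}$ p-values.
Four summaries address the small sample:

* **FDR.** `bh_fdr()` applies the Benjamini–Hochberg step-up rule at
  $q = 0.1$, separately per predictor (via `stats::p.adjust`, with a
  brute-force step-up oracle in the tests).
* **Joint test.** `permutation_wald()` forms $W = b' V^{-1} b$ over the
  11 predictor coefficients. The cross-equation covariance is not
  defined by the source analysis; the choice here estimates $V$ from
  participant-level influence contributions summed over the participants
  each pair of equations shares, which respects the unequal per-outcome
  Ns. Because the $\chi^2_{11}$ reference is anti-conservative at these
  sizes, the p-value is empirical: outcome rows are permuted jointly
  (one permutation per replicate, preserving cross-outcome dependence
  under the null; independent per-outcome permutation is an option),
  $B = 1000$ by default, with the add-one convention $p = (1 +
  \#\{W_b \ge W\})/(B+1)$ so p is never 0.
* **Shrinkage.** `bayes_shrinkage()` combines each coefficient with the
  elicited normal prior — mean 0.15, SD 0.2 for the composite index;
  mean 0.05 for the preschool score, whose prior SD was not separately
  stated and defaults to the same 0.2 (configurable and logged in the
  pipeline manifest). The posterior mean is the precision-weighted
  convex combination; it is the "best guess" effect size, immune to
  significance selection.
* **Averaging.** `average_correlation()` reports the unweighted mean
  coefficient. Signs are taken as-is for the primary batteries (reverse
  scaling already encodes direction); per-item analyses sign-adjust to
  positive first, as their published counterparts do.

`power_check()` reruns the battery over replicate synthetic cohorts to
report the joint-test and FDR power of the design — the simulation the
pre-registration used to justify the battery.

## The synthetic cohort

`generate_cohort()` draws: a latent self-regulation factor $L_i \sim
N(0,1)$; wait times from the tobit model at the published full-cohort
estimates ($\alpha = 2.289$, $\beta_1 = 0.081$, $\beta_2 = -0.673$,
$\sigma_\eta = 0.786$, $\sigma_\varepsilon = 2.469$, censored at 900 s),
with ages $\sim N(52.1, 5.7^2)$ months truncated to 24–72 (the cohort
spanned ages 2–6) and sex Bernoulli(0.48); item ratings $s_j(aL +
\sqrt{1-a^2}e)$ with keying $s_j = \pm 1$ and loading $a = 0.4$; and 11
outcomes $b_k L + \sqrt{1-b_k^2}e$ observed on a 113-participant survey
subsample with the published per-outcome missing counts (0–7,
missing-completely-at-random; whole-battery CCQ non-response at rate
3/113 reproduces the slightly smaller composite-index Ns). A
condition-level share of individual log-wait variance,
`latent_loading_wait`, carries whatever signal the wait task has about
$L$. Six of the 21 conditions (~30% of participants) are flagged
"diagnostic"; `diagnostic_boost` optionally inflates the wait-task
loading there to emulate the hypothesis that only diagnostic variants
reveal competence. One global seed fans out to per-component substreams,
so cohorts are byte-identical under a fixed seed and components can be
regenerated independently.

**Calibration.** The free effect-size parameters were set once, by
simulation against the *full* pipeline (refitting the wait-time model on
every replicate), so that the replicate-mean battery correlations hit
the two headline values: outcome loadings $b_k = 0.212$ give a
composite-index battery mean of ≈ 0.19, and `latent_loading_wait`
$= 0.0113$ gives a preschool-delay battery mean of ≈ 0.02. These are the
package defaults; `calibrate_effect_sizes()` re-derives them (or targets
other values) by iterative proportional adjustment with a
simulation-based verification, and raises a calibration error for
infeasible targets.

**What the generator does not emulate** — hence what passing tests do
not show about real data: survey recruitment and attrition (the survey
subsample is drawn completely at random, whereas the real survey sample
skews female), informative missingness, Likert discreteness and
response styles in the item ratings, non-normal latent structure,
sex-linked outcome differences beyond the wait-time model, and any
causal structure: the latent factor is a device for inducing the target
correlation pattern, not a developmental model.

## Problem sizes in the test suite

The shipped tests exercise the estimator-recovery property at the study
geometry (50 replicate cohorts of n = 543 across 21 conditions), the
joint test's size with 500 null replicates at B = 199, and the full
pipeline's effect-size recovery with 200 replicate cohorts; unit tests
use smaller deterministic fixtures, and the quadrature, imputation and
FDR implementations are each checked against an independent oracle
(grid integration, the inverse-Mills closed form, brute-force step-up).

## Known limitations

* The random-effects tobit assumes a single global censoring limit;
  per-condition limits are out of scope (the limit is configurable).
* Standard errors are observed-information ML; no small-sample
  degrees-of-freedom correction is applied to the wait-time model.
* The joint Wald covariance and the permutation scheme are one
  defensible pair of choices among several the source analysis leaves
  open; both alternatives provided (`scheme = "per_outcome"`,
  complete-case indices) should be reported alongside when results are
  sensitive to them.
* Bootstrap SEs for average correlations resample participants and
  re-run the battery; they do not propagate uncertainty in the
  wait-time model parameters into RND.
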