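Package: capform
Title: Life-Course Self-Regulation and Mid-Life Capital Formation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable implementation of a pre-registered analysis
    pipeline linking life-course self-regulation measures to mid-life capital
    formation. Provides construction of the rank-normalized delay (RND) score
    from censored preschool wait times via a maximum-likelihood random-effects
    tobit model with empirical-Bayes condition effects, rank-based inverse
    normal transformation utilities, composite self-regulation (RNSRI) and
    capital-formation index construction, and a small-sample inference battery:
    per-outcome OLS with controls, Benjamini-Hochberg FDR, a permutation-based
    joint Wald test, conjugate normal-normal Bayesian shrinkage, and Monte
    Carlo power checks. A synthetic-cohort generator with the statistical
    structure the analysis assumes (censored log-normal wait times with
    condition-level random effects, latent-factor item batteries, and outcome
    variables with configurable loadings and missingness) makes every stage
    testable without access to the confidential longitudinal cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
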