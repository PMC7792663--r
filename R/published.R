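#' Reported association battery from the Bing mid-life survey
#'
#' The published per-outcome OLS coefficients (correlation scale), standard
#' errors and sample sizes for the two pre-registered predictors - the
#' composite self-regulation index (RNSRI) and the preschool rank-normalized
#' delay score (RND) - against the 11 capital formation outcomes, each
#' regression controlling for sex (the savings-rate regression additionally
#' for permanent income). These printed estimates are shipped as data: the
#' underlying cohort is confidential, but the battery's summary operations
#' (average coefficient, FDR discoveries, Bayesian shrinkage) can be
#' recomputed from them exactly.
#'
#' @param predictor `"rnsri"`, `"rnd"`, or `"both"` (default).
#' @return data frame with `outcome`, `predictor`, `estimate`, `se`, `n`,
#'   and `controls` (number of regressors besides the outcome: intercept,
#'   predictor, sex, plus permanent income for savings rate).
#' @export
published_associations <- function(predictor = c("both", "rnsri", "rnd")) {
  predictor <- match.arg(predictor)
  out <- outcome_names()
  k <- ifelse(out == "savings_rate", 4L, 3L)
  tab <- rbind(
    data.frame(
      outcome = out, predictor = "rnsri",
      estimate = c(0.31, 0.32, 0.09, 0.09, 0.18, 0.16, -0.01, 0.24, 0.24,
                   0.35, 0.14),
      se = c(0.10, 0.09, 0.10, 0.08, 0.08, 0.09, 0.09, 0.09, 0.09, 0.09,
             0.09),
      n = c(106L, 109L, 106L, 106L, 110L, 109L, 103L, 110L, 110L, 110L,
            110L),
      k = k, stringsAsFactors = FALSE
    ),
    data.frame(
      outcome = out, predictor = "rnd",
      estimate = c(0.09, -0.08, 0.15, -0.01, 0.04, 0.09, -0.06, -0.07,
                   0.13, 0.09, -0.13),
      se = c(0.10, 0.10, 0.10, 0.08, 0.08, 0.09, 0.09, 0.09, 0.09, 0.09,
             0.09),
      n = c(109L, 112L, 109L, 109L, 113L, 112L, 106L, 113L, 113L, 113L,
            113L),
      k = k, stringsAsFactors = FALSE
    )
  )
  row.names(tab) <- NULL
  if (predictor != "both") tab <- tab[tab$predictor == predictor, ]
  tab
}

#' Summarize a reported association battery
#'
#' Reconstructs, from printed (coefficient, SE, N) triples, the battery's
#' summary statistics: the mean coefficient, the sign counts, two-sided
#' p-values from the t distribution with `n - k` degrees of freedom, the
#' BH-FDR discovery set at level `q`, and the normal-normal posterior means
#' under the elicited prior.
#'
#' @param tab data frame as returned by [published_associations()] for a
#'   single predictor (columns `outcome`, `estimate`, `se`, `n`, `k`).
#' @param prior a [prior_spec()].
#' @param q FDR level.
#' @return list with `mean_r`, `mean_posterior`, `n_positive`,
#'   `discoveries` (outcome names), and the augmented table.
#' @export
summarize_published <- function(tab, prior = prior_spec(), q = 0.1) {
  stopifnot(all(c("estimate", "se", "n", "k") %in% names(tab)))
  t_stat <- tab$estimate / tab$se
  tab$p <- 2 * stats::pt(-abs(t_stat), df = tab$n - tab$k)
  tab$fdr_discovery <- bh_fdr(tab$p, q = q)
  post <- bayes_shrinkage(tab$estimate, tab$se, prior)
  tab$posterior_mean <- post$posterior_mean
  tab$posterior_sd <- post$posterior_sd
  list(
    mean_r = average_correlation(tab),
    mean_posterior = mean(tab$posterior_mean),
    n_positive = sum(tab$estimate > 0),
    discoveries = tab$outcome[tab$fdr_discovery],
    table = tab
  )
}
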