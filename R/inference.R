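# ---- OLS association --------------------------------------------------------

#' Association between one outcome and one self-regulation predictor
#'
#' OLS of the outcome on the predictor, an intercept, a sex control, and any
#' extra controls (the savings-rate regression additionally controls for
#' permanent income), on the complete cases for that outcome. With both
#' variables rank-normalized the coefficient is on the correlation scale.
#' The standard error is the conventional homoskedastic one; the two-sided
#' p-value uses the t distribution with `N - k` degrees of freedom.
#'
#' @param outcome,predictor numeric score vectors.
#' @param sex 0/1 vector.
#' @param extra_controls optional numeric vector, matrix or data frame of
#'   additional controls.
#' @param outcome_name,predictor_name labels carried into the result.
#' @return one-row data frame: `outcome`, `predictor`, `estimate`, `se`,
#'   `t`, `p`, `n`, `controls`.
#' @export
ols_assoc <- function(outcome, predictor, sex, extra_controls = NULL,
                      outcome_name = "outcome",
                      predictor_name = "predictor") {
  Xe <- NULL
  ctrl <- "sex"
  if (!is.null(extra_controls)) {
    Xe <- as.matrix(extra_controls)
    ctrl <- paste(c("sex", colnames(Xe) %||% "extra"), collapse = "+")
  }
  X <- cbind(`(Intercept)` = 1, predictor = predictor, sex = sex, Xe)
  ok <- stats::complete.cases(X) & !is.na(outcome)
  n <- sum(ok)
  k <- ncol(X)
  if (n < max(10L, k + 1L))
    stop("too few complete cases (", n, ") for ", outcome_name)
  X <- X[ok, , drop = FALSE]
  y <- outcome[ok]
  qx <- qr(X)
  if (qx$rank < k)
    stop("collinear design for ", outcome_name)
  b <- qr.coef(qx, y)
  r <- y - X %*% b
  s2 <- sum(r^2) / (n - k)
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(s2 * XtXinv[2L, 2L])
  tval <- b[["predictor"]] / se
  data.frame(
    outcome = outcome_name, predictor = predictor_name,
    estimate = b[["predictor"]], se = se, t = tval,
    p = 2 * stats::pt(-abs(tval), n - k), n = n, controls = ctrl,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- FDR --------------------------------------------------------------------

#' Benjamini-Hochberg discoveries at a given FDR level
#'
#' Step-up rule: with sorted p-values \eqn{p_{(1)} \le \dots \le p_{(m)}},
#' reject all hypotheses with sorted index at most
#' \eqn{\max\{i : p_{(i)} \le i q / m\}}. Implemented through
#' [stats::p.adjust()] (`"BH"`), which is equivalent.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @param q FDR level (default 0.1, the pre-registered threshold).
#' @return logical vector of discovery flags.
#' @export
bh_fdr <- function(pvalues, q = 0.1) {
  if (length(pvalues) == 0L) stop("empty p-value vector")
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH") <= q
}

# ---- Bayesian shrinkage -----------------------------------------------------

#' Elicited normal prior for a correlation-scale coefficient
#'
#' @param mean prior mean (default 0.15, the pre-registered prior for the
#'   composite self-regulation index; the preschool-delay measure used a
#'   prior mean of 0.05).
#' @param sd prior standard deviation (default 0.2).
#' @return list of class `"prior_spec"`.
#' @export
prior_spec <- function(mean = 0.15, sd = 0.2) {
  stopifnot(sd > 0)
  structure(list(mean = mean, sd = sd), class = "prior_spec")
}

#' Conjugate normal-normal shrinkage of an estimated coefficient
#'
#' Treats the OLS coefficient as normally distributed around the true effect
#' with its standard error, and combines it with a normal prior:
#' posterior precision \eqn{1/\tau^2 + 1/\mathrm{SE}^2}, posterior mean the
#' precision-weighted average of prior mean and estimate. The posterior
#' mean is a convex combination of the two and is free of the small-sample
#' "winner's curse" exaggeration that affects significance-filtered
#' estimates.
#'
#' @param estimate,se coefficient estimate(s) and standard error(s);
#'   vectors are processed elementwise.
#' @param prior a [prior_spec()].
#' @return data frame with `posterior_mean` and `posterior_sd`.
#' @examples
#' bayes_shrinkage(0.31, 0.10, prior_spec(0.15, 0.2))  # mean 0.278
#' @export
bayes_shrinkage <- function(estimate, se, prior = prior_spec()) {
  stopifnot(inherits(prior, "prior_spec"))
  if (any(se <= 0)) stop("standard errors must be positive")
  prec <- 1 / prior$sd^2 + 1 / se^2
  data.frame(
    posterior_mean = (prior$mean / prior$sd^2 + estimate / se^2) / prec,
    posterior_sd = sqrt(1 / prec)
  )
}

# ---- joint Wald test with permutation calibration ---------------------------

# Joint Wald statistic that the predictor coefficient is zero in all m
# outcome equations. Each equation is estimated by OLS on its own complete
# cases; the cross-equation covariance of the m predictor coefficients is
# assembled from participant-level influence contributions
# psi_ij = e' (X_j'X_j)^{-1} x_ij r_ij, summed over participants shared by
# each pair of equations (a shared-sample robust covariance). Returns
# b' V^{-1} b.
wald_stat <- function(Y, predictor, sex, extra_controls = NULL) {
  n <- nrow(Y); m <- ncol(Y)
  b <- numeric(m)
  Psi <- matrix(0, n, m)
  for (j in seq_len(m)) {
    Xe <- extra_controls[[colnames(Y)[j]]]
    X <- cbind(1, predictor, sex, if (!is.null(Xe)) as.matrix(Xe))
    ok <- stats::complete.cases(X) & !is.na(Y[, j])
    Xj <- X[ok, , drop = FALSE]
    qx <- qr(Xj)
    if (qx$rank < ncol(Xj))
      stop("collinear design in equation ", colnames(Y)[j])
    bj <- qr.coef(qx, Y[ok, j])
    r <- Y[ok, j] - Xj %*% bj
    A <- chol2inv(qr.R(qx))          # (X'X)^-1
    infl <- (Xj %*% A[, 2L]) * r     # influence on predictor coefficient
    b[j] <- bj[2L]
    Psi[ok, j] <- infl
  }
  V <- crossprod(Psi)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < max(ev) * 1e-12)
    stop("degenerate cross-equation covariance (condition number ",
         format(max(ev) / max(min(ev), .Machine$double.xmin), digits = 3),
         ")")
  drop(crossprod(b, solve(V, b)))
}

#' Permutation-calibrated joint Wald test
#'
#' Tests the joint null that the predictor is unrelated to all outcomes.
#' The observed statistic is a Wald form \eqn{b' V^{-1} b} over the m
#' per-outcome predictor coefficients, with `V` estimated from shared
#' participant-level influence contributions (so equations estimated on
#' overlapping but unequal samples are handled). Because the asymptotic
#' chi-square reference is anti-conservative at these sample sizes, the
#' p-value is calibrated by permutation: outcome rows are permuted `B`
#' times (by default jointly, one permutation per replicate, preserving the
#' cross-outcome dependence under the null) and the empirical p-value is
#' `(1 + #(perm >= observed)) / (B + 1)`.
#'
#' @param outcomes numeric matrix (participants by outcomes), `NA` allowed.
#' @param predictor,sex numeric vectors aligned with the rows.
#' @param extra_controls named list: for an outcome name, a vector/matrix
#'   of additional controls for that equation.
#' @param B number of permutations (>= 99; default 1000).
#' @param seed optional integer seed for the permutations.
#' @param scheme `"joint"` permutes all outcome columns with one shared
#'   row permutation; `"per_outcome"` permutes each column independently.
#' @return list of class `"joint_wald"`: `statistic`, `perm_stats`,
#'   `p_value`, `B`, `scheme`, `seed`.
#' @export
permutation_wald <- function(outcomes, predictor, sex,
                             extra_controls = NULL, B = 1000L,
                             seed = NULL,
                             scheme = c("joint", "per_outcome")) {
  scheme <- match.arg(scheme)
  if (B < 99L) stop("B must be at least 99")
  Y <- as.matrix(outcomes)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  obs <- wald_stat(Y, predictor, sex, extra_controls)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- nrow(Y)
  perm_stats <- vapply(seq_len(B), function(b) {
    Yp <- if (scheme == "joint") {
      Y[sample.int(n), , drop = FALSE]
    } else {
      apply(Y, 2L, function(col) col[sample.int(n)])
    }
    wald_stat(Yp, predictor, sex, extra_controls)
  }, numeric(1))
  structure(list(
    statistic = obs,
    perm_stats = perm_stats,
    p_value = (1 + sum(perm_stats >= obs)) / (B + 1),
    B = B, scheme = scheme, seed = seed
  ), class = "joint_wald")
}

#' @export
print.joint_wald <- function(x, ...) {
  cat(sprintf(
    "Joint Wald test: W = %.2f, empirical p = %.4g (B = %d, %s permutation)\n",
    x$statistic, x$p_value, x$B, x$scheme))
  invisible(x)
}

# ---- summaries --------------------------------------------------------------

#' Average coefficient across an association battery
#'
#' Unweighted mean of the per-outcome coefficients. For the primary
#' batteries, signs are taken as-is: reverse scaling of unfavourable
#' outcomes already encodes the expected direction. For per-item analyses,
#' `sign_adjust = TRUE` makes every coefficient positive before averaging.
#'
#' @param assocs data frame of [ols_assoc()] rows (needs an `estimate`
#'   column).
#' @param sign_adjust adjust each coefficient to be positive first?
#' @return the mean coefficient.
#' @export
average_correlation <- function(assocs, sign_adjust = FALSE) {
  if (NROW(assocs) < 1L) stop("need at least one association")
  est <- assocs$estimate
  if (sign_adjust) est <- abs(est)
  mean(est)
}

#' Run the full pre-registered association battery
#'
#' For one predictor: per-outcome OLS with sex control (plus permanent
#' income for the savings-rate equation), BH-FDR discovery flags at level
#' `q`, the permutation-calibrated joint Wald test, normal-normal posterior
#' summaries under the elicited prior, the average coefficient, and a
#' participant-level bootstrap SE for that average (resampling rows and
#' re-running all regressions).
#'
#' @param tbl analysis table from [build_analysis_table()] (or any data
#'   frame with the referenced columns).
#' @param predictor column name of the predictor score (e.g. `"rnsri"`,
#'   `"rnd"`).
#' @param outcomes outcome column names (default the 11-outcome battery).
#' @param sex_col sex column name.
#' @param extra_controls named list mapping an outcome to control column
#'   names; default controls the savings-rate equation for permanent
#'   income.
#' @param prior a [prior_spec()] for the shrinkage summaries.
#' @param q FDR level.
#' @param wald_B permutations for the joint test; 0 skips it.
#' @param bootstrap_B bootstrap replicates for the SE of the average
#'   coefficient; 0 skips it.
#' @param seed optional seed governing the permutation and bootstrap draws.
#' @return list of class `"battery_result"`: `assoc` (association table
#'   with FDR flags and posterior summaries), `mean_r`, `mean_r_se`
#'   (bootstrap, or `NA`), `mean_posterior`, `joint` (a `"joint_wald"` or
#'   `NULL`), and the settings used.
#' @export
run_battery <- function(tbl, predictor,
                        outcomes = outcome_names(),
                        sex_col = "male",
                        extra_controls = list(
                          savings_rate = "permanent_income"),
                        prior = prior_spec(),
                        q = 0.1, wald_B = 1000L, bootstrap_B = 1000L,
                        seed = NULL) {
  stopifnot(predictor %in% names(tbl), all(outcomes %in% names(tbl)))
  ctrl_of <- function(d, o) {
    cols <- extra_controls[[o]]
    if (is.null(cols)) NULL
    else as.matrix(stats::setNames(d[cols], cols))
  }
  one_pass <- function(d) {
    do.call(rbind, lapply(outcomes, function(o) {
      ols_assoc(d[[o]], d[[predictor]], d[[sex_col]], ctrl_of(d, o),
                outcome_name = o, predictor_name = predictor)
    }))
  }
  assoc <- one_pass(tbl)
  assoc$fdr_discovery <- bh_fdr(assoc$p, q = q)
  post <- bayes_shrinkage(assoc$estimate, assoc$se, prior)
  assoc$posterior_mean <- post$posterior_mean
  assoc$posterior_sd <- post$posterior_sd

  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  joint <- NULL
  if (wald_B > 0L) {
    Y <- as.matrix(tbl[outcomes])
    ec <- lapply(stats::setNames(nm = outcomes), function(o)
      ctrl_of(tbl, o))
    ec <- Filter(Negate(is.null), ec)
    joint <- permutation_wald(Y, tbl[[predictor]], tbl[[sex_col]],
                              extra_controls = ec, B = wald_B)
  }
  mean_r_se <- NA_real_
  if (bootstrap_B > 0L) {
    n <- nrow(tbl)
    boots <- vapply(seq_len(bootstrap_B), function(b) {
      d <- tbl[sample.int(n, replace = TRUE), , drop = FALSE]
      mean(vapply(outcomes, function(o) {
        tryCatch(
          ols_assoc(d[[o]], d[[predictor]], d[[sex_col]], ctrl_of(d, o),
                    outcome_name = o)$estimate,
          error = function(e) NA_real_)
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    mean_r_se <- stats::sd(boots, na.rm = TRUE)
  }
  structure(list(
    assoc = assoc,
    mean_r = average_correlation(assoc),
    mean_r_se = mean_r_se,
    mean_posterior = mean(assoc$posterior_mean),
    joint = joint,
    predictor = predictor, q = q, prior = prior
  ), class = "battery_result")
}

#' @export
print.battery_result <- function(x, digits = 2, ...) {
  cat("Association battery for predictor:", x$predictor, "\n")
  tab <- x$assoc
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$p <- signif(tab$p, 2)
  tab$posterior_mean <- round(tab$posterior_mean, digits)
  print(tab[c("outcome", "estimate", "se", "p", "n", "fdr_discovery",
              "posterior_mean")], row.names = FALSE, ...)
  cat(sprintf("mean coefficient = %.*f", digits, x$mean_r))
  if (!is.na(x$mean_r_se))
    cat(sprintf(" (bootstrap SE %.*f)", digits, x$mean_r_se))
  cat(sprintf("; mean posterior = %.*f\n", digits, x$mean_posterior))
  if (!is.null(x$joint)) print(x$joint)
  invisible(x)
}

#' Battery comparison between diagnostic and non-diagnostic participants
#'
#' Runs the association battery separately within the two groups defined by
#' a logical flag and reports the difference of their average coefficients
#' with a bootstrap standard error (participants resampled within group).
#'
#' @param tbl analysis table.
#' @param predictor predictor column (typically `"rnd"`).
#' @param group_col logical column splitting the sample.
#' @param bootstrap_B bootstrap replicates for the difference SE.
#' @param seed optional seed.
#' @param ... passed to [run_battery()] (e.g. `outcomes`, `q`).
#' @return list with per-group `"battery_result"`s (`group_true`,
#'   `group_false`), `diff_mean_r` and `diff_se`.
#' @export
subgroup_analysis <- function(tbl, predictor, group_col = "diagnostic",
                              bootstrap_B = 500L, seed = NULL, ...) {
  flag <- as.logical(tbl[[group_col]])
  if (sum(flag, na.rm = TRUE) < 10L || sum(!flag, na.rm = TRUE) < 10L)
    stop("each group needs at least 10 participants")
  if (!is.null(seed)) set.seed(seed)
  d1 <- tbl[which(flag), , drop = FALSE]
  d0 <- tbl[which(!flag), , drop = FALSE]
  b1 <- run_battery(d1, predictor, wald_B = 0L, bootstrap_B = bootstrap_B,
                    ...)
  b0 <- run_battery(d0, predictor, wald_B = 0L, bootstrap_B = bootstrap_B,
                    ...)
  diff_se <- if (bootstrap_B > 0L)
    sqrt(b1$mean_r_se^2 + b0$mean_r_se^2) else NA_real_
  list(group_true = b1, group_false = b0,
       diff_mean_r = b1$mean_r - b0$mean_r, diff_se = diff_se)
}

#' Monte Carlo power check for the pre-registered battery
#'
#' Simulates replicate cohorts under a specification, runs the battery for
#' a predictor on each, and reports the fraction of replicates in which
#' (i) the permutation joint Wald test rejects at `alpha` and (ii) at least
#' one outcome is a BH-FDR discovery at level `q`. Effect sizes are
#' whatever the supplied spec encodes (set its loadings to the prior-mean
#' effects to reproduce a design-stage power analysis; set them to zero to
#' check size).
#'
#' @param spec a [cohort_spec()].
#' @param predictor `"rnsri"` or `"rnd"`.
#' @param n_reps replicate cohorts.
#' @param wald_B permutations per replicate (kept moderate for speed).
#' @param q FDR level; `alpha` joint-test level.
#' @param seed integer seed (fans out per replicate).
#' @param refit_wait_model refit the tobit model on every replicate
#'   (`TRUE`), or evaluate the empirical-Bayes expectations at the
#'   generating parameters (`FALSE`, much faster; appropriate when the
#'   question is battery power rather than estimation uncertainty).
#' @param n_draws Monte Carlo draws for censored-wait imputation per
#'   replicate.
#' @return list with `power_wald`, `power_fdr`, `n_reps` and the
#'   per-replicate summary table.
#' @export
power_check <- function(spec, predictor = "rnsri", n_reps = 100L,
                        wald_B = 199L, q = 0.1, alpha = 0.05, seed = 1L,
                        refit_wait_model = FALSE, n_draws = 2000L) {
  if (n_reps < 1L) stop("n_reps must be positive")
  reps <- replicate_batteries(spec, n_reps = n_reps, seed = seed,
                              refit = refit_wait_model, wald_B = wald_B,
                              q = q, predictors = predictor,
                              n_draws = n_draws)
  # with the add-one permutation convention, rejecting at p <= alpha has
  # exact size floor(alpha * (B + 1)) / (B + 1)
  list(
    power_wald = mean(reps$wald_p <= alpha),
    power_fdr = mean(reps$n_fdr > 0),
    n_reps = n_reps,
    replicates = reps
  )
}

# Shared replicate harness: generate cohort -> RND -> indices -> battery.
# Returns one row per replicate x predictor with the mean coefficient, the
# joint-test p (if wald_B > 0) and the FDR discovery count.
replicate_batteries <- function(spec, n_reps, seed, refit = TRUE,
                                wald_B = 0L, q = 0.1,
                                predictors = c("rnsri", "rnd"),
                                n_draws = 2000L, n_quad = 21L) {
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- (seed * 1000L + r) %% .Machine$integer.max
    sp <- spec
    sp$seed <- rep_seed
    coh <- generate_cohort(sp)
    fit <- if (refit) fit_tobit_re(coh$wait_records,
                                   censor_seconds = sp$tobit$censor_seconds,
                                   n_quad = n_quad)
    else tobit_fit_fixed(coh$wait_records, sp$tobit, n_quad = n_quad)
    rnd <- compute_rnd(coh$wait_records, fit, n_draws = n_draws,
                       seed = rep_seed + 1L)
    tbl <- build_analysis_table(coh, rnd)
    rows <- lapply(predictors, function(p) {
      bat <- run_battery(tbl, p, wald_B = wald_B, bootstrap_B = 0L,
                         q = q, seed = rep_seed + 2L)
      data.frame(rep = r, predictor = p, mean_r = bat$mean_r,
                 wald_p = if (is.null(bat$joint)) NA_real_
                          else bat$joint$p_value,
                 n_fdr = sum(bat$assoc$fdr_discovery),
                 stringsAsFactors = FALSE)
    })
    out[[r]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}
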