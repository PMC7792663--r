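test_that("quadrature matches brute-force grid integration of the marginal likelihood", {
  rec <- make_wait_records(n = 36, n_cond = 3, alpha = 5.2, sigma_eta = 0.7,
                           sigma_eps = 1.2, censor = 600, seed = 41)
  expect_gt(sum(rec$censored), 2)   # fixture exercises both branches
  par <- tobit_params(alpha = 5.2, beta_age = 0.04, beta_male = -0.4,
                      sigma_eta = 0.7, sigma_eps = 1.2,
                      censor_seconds = 600)
  fit <- tobit_fit_fixed(rec, par)
  oracle <- grid_marginal(rec, par, censor = 600)
  expect_equal(fit$loglik, oracle$logL, tolerance = 1e-7)
  expect_equal(fit$eb$eb_eta, oracle$eb, tolerance = 1e-6)
})

test_that("without censoring or heterogeneity the fit collapses to least squares", {
  rec <- make_wait_records(n = 400, n_cond = 8, alpha = 3, sigma_eta = 0,
                           sigma_eps = 1, censor = 1e8, seed = 42)
  expect_false(any(rec$censored))
  fit <- fit_tobit_re(rec, censor_seconds = 1e8)
  ols <- lm(log(wait_seconds) ~ age_months + male, data = rec)
  expect_equal(unname(fit$coefficients),
               unname(coef(ols)), tolerance = 0.02)
  expect_equal(fit$sigma_eps,
               sqrt(sum(resid(ols)^2) / nrow(rec)), tolerance = 0.02)
  expect_lt(fit$sigma_eta, 0.1)
})

test_that("the fit is a deterministic function of the data", {
  rec <- make_wait_records(seed = 43)
  f1 <- fit_tobit_re(rec)
  f2 <- fit_tobit_re(rec)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$eb$eb_eta, f2$eb$eb_eta)
})

test_that("log-likelihood is invariant to condition relabeling and shifts with the scale", {
  rec <- make_wait_records(n = 150, n_cond = 5, seed = 44)
  fit <- fit_tobit_re(rec)
  rec2 <- rec
  rec2$condition <- chartr("c", "z", rec$condition)  # relabel
  fit2 <- fit_tobit_re(rec2)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-6)

  # multiplying waits (and the censor point) by e shifts alpha by 1 and
  # leaves slopes and SDs unchanged
  rec3 <- rec
  rec3$wait_seconds <- rec$wait_seconds * exp(1)
  fit3 <- fit_tobit_re(rec3, censor_seconds = 900 * exp(1))
  expect_equal(fit3$coefficients[["alpha"]],
               fit$coefficients[["alpha"]] + 1, tolerance = 1e-3)
  expect_equal(fit3$coefficients[["beta_age"]],
               fit$coefficients[["beta_age"]], tolerance = 1e-4)
  expect_equal(fit3$sigma_eps, fit$sigma_eps, tolerance = 1e-3)
  expect_equal(fit3$sigma_eta, fit$sigma_eta, tolerance = 1e-3)
})

test_that("empirical-Bayes condition effects shrink toward zero", {
  # two conditions with the same raw mean residual but different sizes:
  # the small condition is shrunk harder; a large baseline condition pins
  # the fixed effects
  set.seed(45)
  base <- data.frame(
    participant_id = sprintf("b%03d", 1:60),
    condition = "base", age_months = 50, male = 0,
    wait_seconds = exp(pmin(rnorm(60, 4, 1), log(900) - 0.01)),
    censored = FALSE,
    stringsAsFactors = FALSE
  )
  mk <- function(id, n, shift) data.frame(
    participant_id = sprintf("%s%02d", id, seq_len(n)),
    condition = id, age_months = 50, male = 0,
    wait_seconds = exp(4 + shift), censored = FALSE,
    stringsAsFactors = FALSE
  )
  rec <- rbind(base, mk("big", 20, 1.5), mk("small", 3, 1.5))
  fit <- tobit_fit_fixed(rec, tobit_params(
    alpha = 4, beta_age = 0, beta_male = 0, sigma_eta = 0.6,
    sigma_eps = 1))
  eb <- setNames(fit$eb$eb_eta, fit$eb$condition)
  expect_gt(eb[["big"]], 0)
  expect_gt(eb[["small"]], 0)
  expect_lt(eb[["small"]], eb[["big"]])     # smaller n, more shrinkage
  expect_lt(eb[["big"]], 1.5)               # strictly below raw deviation
})

test_that("expected log wait is the fixed part plus the condition effect", {
  rec <- make_wait_records(n = 120, n_cond = 4, seed = 46)
  fit <- fit_tobit_re(rec)
  b <- fit$coefficients
  eb <- setNames(fit$eb$eb_eta, fit$eb$condition)
  manual <- b[["alpha"]] + b[["beta_age"]] * rec$age_months +
    b[["beta_male"]] * rec$male + eb[rec$condition]
  expect_equal(expected_ln_wait(fit, rec), unname(manual))
  expect_error(expected_ln_wait(fit, transform(rec, condition = "nope")),
               "unknown condition")
  # under the ML fit the EB condition effects average out near zero
  expect_lt(abs(weighted.mean(fit$eb$eb_eta, fit$eb$n)), 0.1)
})

test_that("censored imputation matches the inverse-Mills closed form", {
  for (mu in c(6.0, 6.8)) {
    for (s in c(1, 2.5)) {
      fit <- make_flat_fit(mu, s)
      rec <- data.frame(condition = "a", age_months = 50, male = 0,
                        censored = TRUE)
      nd <- 20000
      est <- impute_censored_ln_wait(fit, rec, n_draws = nd, seed = 47)
      a <- (log(900) - mu) / s
      lam <- dnorm(a) / pnorm(a, lower.tail = FALSE)
      truth <- mu + s * lam
      sd_trunc <- s * sqrt(1 + a * lam - lam^2)
      expect_lt(abs(est - truth), 3 * sd_trunc / sqrt(nd))
      expect_gt(est, log(900))
    }
  }
})

test_that("imputation limits and contract errors behave", {
  # truncation far below the mean barely binds
  fit <- make_flat_fit(log(900) + 8, 1)
  rec <- data.frame(condition = "a", age_months = 50, male = 0,
                    censored = TRUE)
  est <- impute_censored_ln_wait(fit, rec, n_draws = 5000, seed = 48)
  expect_equal(est, log(900) + 8, tolerance = 0.05)
  # calling on an uncensored record is a contract violation
  rec$censored <- FALSE
  expect_error(impute_censored_ln_wait(fit, rec), "uncensored")
  # the posterior-eta mode also respects the truncation bound
  rec$censored <- TRUE
  est2 <- impute_censored_ln_wait(fit, rec, n_draws = 2000, seed = 49,
                                  eta = "posterior")
  expect_gt(est2, log(900))
})

test_that("RND deviations are residuals and respect rank structure", {
  rec <- make_wait_records(n = 150, n_cond = 5, censor = 1e8, seed = 50)
  fit <- fit_tobit_re(rec, censor_seconds = 1e8)
  rnd <- compute_rnd(rec, fit)
  # no censoring: deviations are exactly observed minus expected
  expect_equal(rnd$deviation,
               log(rec$wait_seconds) - expected_ln_wait(fit, rec))
  expect_identical(order(rnd$rnd), order(rnd$deviation))
  # rank normalization of the deviations
  expect_equal(rnd$rnd, rank_inverse_normal(rnd$deviation))
  # deviations centre near zero in the estimation sample
  expect_lt(abs(mean(rnd$deviation)), 0.15)
})

test_that("duplicate participants keep the first record with a warning", {
  rec <- make_wait_records(n = 80, n_cond = 4, seed = 51)
  dup <- rec[c(seq_len(80), 3), ]
  dup$wait_seconds[81] <- 5  # later record differs
  expect_warning(fit <- fit_tobit_re(dup), "duplicate")
  expect_equal(coef(fit), coef(fit_tobit_re(rec)))
})

test_that("degenerate designs are rejected", {
  rec <- make_wait_records(n = 60, n_cond = 3, seed = 52)
  rec$condition <- "c01"
  expect_error(fit_tobit_re(rec), "single condition|not identified")
  rec2 <- make_wait_records(n = 60, n_cond = 3, seed = 53)
  rec2$wait_seconds <- 900
  rec2$censored <- TRUE
  expect_error(fit_tobit_re(rec2), "censored")
})
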