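test_that("OLS association matches a hand-rolled normal-equations oracle", {
  set.seed(71)
  n <- 20
  sex <- rep(0:1, 10)
  x <- rnorm(n)
  y <- 0.5 * x - 0.3 * sex + rnorm(n)
  a <- ols_assoc(y, x, sex, outcome_name = "y", predictor_name = "x")

  X <- cbind(1, x, sex)
  b <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% b
  s2 <- sum(r^2) / (n - 3)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(a$estimate, as.numeric(b[2, 1]))
  expect_equal(a$se, se)
  expect_equal(a$p, as.numeric(2 * pt(-abs(b[2, 1] / se), n - 3)))
  expect_equal(a$n, n)

  # and agrees with lm() including an extra control
  z <- rnorm(n)
  a2 <- ols_assoc(y, x, sex, extra_controls = cbind(z = z))
  f <- summary(lm(y ~ x + sex + z))$coefficients
  expect_equal(a2$estimate, f["x", 1])
  expect_equal(a2$se, f["x", 2])
  expect_equal(a2$p, f["x", 4])
})

test_that("OLS association recovers a generative slope and rejects bad designs", {
  set.seed(72)
  n <- 5000
  x <- rnorm(n); sex <- rbinom(n, 1, 0.4)
  y <- 0.3 * x + rnorm(n)
  a <- ols_assoc(y, x, sex)
  expect_lt(abs(a$estimate - 0.3), 3 * a$se)
  # orthogonal predictor: slope near zero
  a0 <- ols_assoc(rnorm(n), x, sex)
  expect_lt(abs(a0$estimate), 3 * a0$se)
  # collinear design
  expect_error(ols_assoc(y, x, sex, extra_controls = cbind(s2 = sex)),
               "collinear")
  # too few complete cases
  expect_error(ols_assoc(c(y[1:8], rep(NA, n - 8)), x, sex), "few")
})

test_that("BH step-up flags match the definition", {
  expect_identical(bh_fdr(c(0.001, 0.02, 0.04, 0.2), q = 0.1),
                   c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(bh_fdr(rep(1, 6)), rep(FALSE, 6))
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")

  # brute-force oracle over random p-vectors
  brute <- function(p, q) {
    m <- length(p)
    s <- sort(p)
    k <- suppressWarnings(max(which(s <= seq_len(m) * q / m)))
    if (!is.finite(k)) rep(FALSE, m) else p <= s[k]
  }
  set.seed(73)
  for (i in 1:1000) {
    m <- sample(1:20, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- sample(c(0.05, 0.1, 0.25), 1)
    expect_identical(bh_fdr(p, q), brute(p, q))
  }
})

test_that("normal-normal shrinkage is conjugate and convex", {
  # worked example: coefficient 0.31 (SE 0.10) under prior (0.15, 0.2)
  post <- bayes_shrinkage(0.31, 0.10, prior_spec(0.15, 0.2))
  expect_equal(post$posterior_mean, (0.15 / 0.04 + 0.31 / 0.01) /
                 (1 / 0.04 + 1 / 0.01))
  expect_equal(post$posterior_mean, 0.278, tolerance = 1e-10)

  # flat-prior and no-data limits
  expect_equal(bayes_shrinkage(0.31, 0.1, prior_spec(0, 1e8))$posterior_mean,
               0.31, tolerance = 1e-6)
  expect_equal(bayes_shrinkage(0.31, 1e8, prior_spec(0.15, 0.2))$posterior_mean,
               0.15, tolerance = 1e-6)

  # convex combination with weights summing to one, on random inputs
  set.seed(74)
  for (i in 1:50) {
    est <- rnorm(1); se <- runif(1, 0.01, 2)
    pm <- rnorm(1); ps <- runif(1, 0.01, 2)
    post <- bayes_shrinkage(est, se, prior_spec(pm, ps))
    w <- (post$posterior_mean - pm) / (est - pm)
    expect_gt(w, 0); expect_lt(w, 1)
    expect_equal(post$posterior_mean, w * est + (1 - w) * pm)
    expect_lt(post$posterior_sd, min(ps, se))
  }
})

test_that("average correlation summarizes batteries with optional sign adjustment", {
  assoc <- data.frame(estimate = c(0.2, -0.1, 0.3))
  expect_equal(average_correlation(assoc), mean(c(0.2, -0.1, 0.3)))
  expect_equal(average_correlation(assoc, sign_adjust = TRUE), 0.2)
  expect_error(average_correlation(assoc[0, , drop = FALSE]), "at least one")
})

test_that("permutation Wald test detects an exact copy and is seed-stable", {
  set.seed(75)
  n <- 100
  x <- rnorm(n); sex <- rbinom(n, 1, 0.5)
  Y <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("y", 1:4)))
  # an exact copy of the predictor has zero residuals, so its influence
  # contributions vanish and the covariance degenerates - flagged, not NaN
  Yc <- Y; Yc[, 2] <- x
  expect_error(permutation_wald(Yc, x, sex, B = 99), "degenerate")
  # a near-copy gives an extreme statistic: p pinned at its lower bound
  Y[, 2] <- x + 0.01 * rnorm(n)
  B <- 199
  jt <- permutation_wald(Y, x, sex, B = B, seed = 76)
  expect_equal(jt$p_value, 1 / (B + 1))
  expect_gte(jt$p_value, 1 / (B + 1))
  expect_lte(jt$p_value, 1)
  # same seed, same p; different seed, statistic unchanged
  jt2 <- permutation_wald(Y, x, sex, B = B, seed = 76)
  expect_identical(jt$p_value, jt2$p_value)
  jt3 <- permutation_wald(Y, x, sex, B = B, seed = 99)
  expect_identical(jt3$statistic, jt$statistic)

  # a duplicated outcome column makes the covariance singular
  Ybad <- cbind(Y[, 1:2], dup = Y[, 2])
  expect_error(permutation_wald(Ybad, x, sex, B = 99), "degenerate")
  expect_error(permutation_wald(Y, x, sex, B = 50), "at least 99")

  # per-outcome permutation scheme runs and stays in range
  jt4 <- permutation_wald(Y[, c(1, 3, 4)], x, sex, B = 99, seed = 77,
                          scheme = "per_outcome")
  expect_gte(jt4$p_value, 1 / 100)
  expect_lte(jt4$p_value, 1)
})

test_that("the full battery ties the pieces together on a synthetic cohort", {
  coh <- generate_cohort(cohort_spec(seed = 78))
  fit <- tobit_fit_fixed(coh$wait_records, coh$spec$tobit)
  rnd <- compute_rnd(coh$wait_records, fit, n_draws = 500, seed = 79)
  tbl <- build_analysis_table(coh, rnd)
  bat <- run_battery(tbl, "rnsri", wald_B = 199, bootstrap_B = 100,
                     seed = 80)
  expect_equal(nrow(bat$assoc), 11)
  expect_true(all(bat$assoc$se > 0))
  expect_true(all(bat$assoc$p > 0 & bat$assoc$p <= 1))
  expect_true(all(bat$assoc$n >= 90 & bat$assoc$n <= 113))
  # savings-rate equation carries the permanent-income control
  expect_match(bat$assoc$controls[bat$assoc$outcome == "savings_rate"],
               "permanent_income")
  expect_equal(bat$mean_r, mean(bat$assoc$estimate))
  expect_true(is.finite(bat$mean_r_se) && bat$mean_r_se > 0)
  expect_true(!is.null(bat$joint))
  # posterior means shrink toward the prior
  expect_true(all(abs(bat$assoc$posterior_mean - 0.15) <=
                    abs(bat$assoc$estimate - 0.15) + 1e-12))
})

test_that("subgroup analysis splits and compares batteries", {
  coh <- generate_cohort(cohort_spec(seed = 81))
  fit <- tobit_fit_fixed(coh$wait_records, coh$spec$tobit)
  rnd <- compute_rnd(coh$wait_records, fit, n_draws = 500, seed = 82)
  tbl <- build_analysis_table(coh, rnd)

  # split on a coin flip independent of everything: difference near zero
  set.seed(83)
  tbl$coin <- rbinom(nrow(tbl), 1, 0.5) == 1
  sg <- subgroup_analysis(tbl, "rnd", group_col = "coin",
                          bootstrap_B = 200, seed = 84)
  expect_lt(abs(sg$diff_mean_r), 4 * sg$diff_se)

  # identical groups agree exactly
  tbl2 <- rbind(tbl, tbl)
  tbl2$half <- rep(c(TRUE, FALSE), each = nrow(tbl))
  sg2 <- subgroup_analysis(tbl2, "rnd", group_col = "half",
                           bootstrap_B = 0)
  expect_equal(sg2$diff_mean_r, 0)

  expect_error(subgroup_analysis(tbl[1:15, ], "rnd", group_col = "coin"),
               "at least 10")
})

test_that("latent loading inflated only in diagnostic conditions raises their battery signal", {
  spec <- cohort_spec(latent_loading_wait = 0.02, diagnostic_boost = 10)
  wins <- 0L
  n_rep <- 12L
  for (r in seq_len(n_rep)) {
    sp <- spec; sp$seed <- 900L + r
    coh <- generate_cohort(sp)
    fit <- tobit_fit_fixed(coh$wait_records, sp$tobit)
    rnd <- compute_rnd(coh$wait_records, fit, n_draws = 300,
                       seed = 950L + r)
    tbl <- build_analysis_table(coh, rnd)
    sg <- subgroup_analysis(tbl, "rnd", group_col = "diagnostic",
                            bootstrap_B = 0)
    wins <- wins + (sg$diff_mean_r > 0)
  }
  expect_gte(wins, ceiling(0.8 * n_rep))
})

test_that("power is monotone in effect size and FDR power responds", {
  specs <- list(
    zero = {
      s <- cohort_spec(seed = 1); s$outcome_spec$loading <- 0
      s$latent_loading_wait <- 0; s
    },
    mid = {
      s <- cohort_spec(seed = 1); s$outcome_spec$loading <- 0.15; s
    },
    high = {
      s <- cohort_spec(seed = 1); s$outcome_spec$loading <- 0.35; s
    }
  )
  pw <- vapply(specs, function(s) {
    p <- power_check(s, predictor = "rnsri", n_reps = 15, wald_B = 99,
                     seed = 85, refit_wait_model = FALSE, n_draws = 300)
    c(p$power_wald, p$power_fdr)
  }, numeric(2))
  expect_lte(pw[1, "zero"], pw[1, "high"])
  expect_lte(pw[2, "zero"], pw[2, "mid"])
  expect_lte(pw[2, "mid"] - 1e-9, pw[2, "high"] + 0.2)  # noisy but ordered
  expect_gt(pw[1, "high"], 0.8)   # strong effects are detected
  expect_lt(pw[2, "zero"], 0.3)   # near-null FDR discoveries are rare
})
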