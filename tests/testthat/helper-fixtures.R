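# Small deterministic fixtures used across test files.

# Wait-record table with known linear structure; censoring applied at
# `censor` seconds.
make_wait_records <- function(n = 200, n_cond = 8, alpha = 4, beta_age = 0.05,
                              beta_male = -0.5, sigma_eta = 0.5,
                              sigma_eps = 1.5, censor = 900, seed = 1) {
  set.seed(seed)
  g <- rep(seq_len(n_cond), length.out = n)
  age <- round(runif(n, 36, 68))
  male <- rbinom(n, 1, 0.5)
  eta <- rnorm(n_cond, 0, sigma_eta)
  ystar <- alpha + beta_age * age + beta_male * male + eta[g] +
    rnorm(n, 0, sigma_eps)
  data.frame(
    participant_id = sprintf("p%03d", seq_len(n)),
    condition = sprintf("c%02d", g),
    age_months = age,
    male = male,
    wait_seconds = pmin(exp(ystar), censor),
    censored = ystar >= log(censor),
    stringsAsFactors = FALSE
  )
}

# A fit object with exactly known expectation structure: intercept mu,
# no covariate effects, negligible condition heterogeneity (so the
# empirical-Bayes condition effects are ~0 and expected_ln_wait == mu).
make_flat_fit <- function(mu, sigma_eps, censor = 900) {
  rec <- data.frame(
    participant_id = sprintf("q%02d", 1:8),
    condition = rep(c("a", "b"), each = 4),
    age_months = 50, male = 0,
    wait_seconds = censor, censored = TRUE,
    stringsAsFactors = FALSE
  )
  tobit_fit_fixed(rec, tobit_params(
    alpha = mu, beta_age = 0, beta_male = 0,
    sigma_eta = 1e-6, sigma_eps = sigma_eps, censor_seconds = censor))
}

# Brute-force grid integration of the per-condition marginal likelihood and
# the posterior mean of the condition effect; the independent oracle for
# the adaptive-quadrature implementation.
grid_marginal <- function(records, params, censor = 900,
                          lim = 8, step = 5e-4) {
  eta_grid <- seq(-lim, lim, by = step) * max(params$sigma_eta, 0.5)
  lc <- log(censor)
  conds <- sort(unique(records$condition))
  res <- lapply(conds, function(cc) {
    r <- records[records$condition == cc, ]
    mu <- params$alpha + params$beta_age * r$age_months +
      params$beta_male * r$male
    ll <- vapply(eta_grid, function(e) {
      y <- log(pmax(r$wait_seconds, 1))
      sum(ifelse(r$censored,
                 pnorm((lc - mu - e) / params$sigma_eps,
                       lower.tail = FALSE, log.p = TRUE),
                 dnorm(y, mu + e, params$sigma_eps, log = TRUE)))
    }, numeric(1)) + dnorm(eta_grid, 0, params$sigma_eta, log = TRUE)
    m <- max(ll)
    w <- exp(ll - m)
    list(logL = m + log(sum(w) * step * max(params$sigma_eta, 0.5)),
         eb = sum(eta_grid * w) / sum(w))
  })
  list(logL = sum(vapply(res, `[[`, numeric(1), "logL")),
       eb = vapply(res, `[[`, numeric(1), "eb"))
}
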