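# ---- internal: validation and data prep -------------------------------------

# Required columns for a wait-record table. Wait times of 0 s (child takes the
# reward immediately) are floored at 1 s before taking logs: ln(0) is
# undefined and 1 s is below any behaviourally meaningful wait.
validate_wait_records <- function(records, censor_seconds) {
  need <- c("participant_id", "condition", "age_months", "male",
            "wait_seconds", "censored")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("wait records missing columns: ", paste(miss, collapse = ", "))
  if (any(records$wait_seconds < 0, na.rm = TRUE))
    stop("negative wait times")
  if (any(records$censored & abs(records$wait_seconds - censor_seconds) > 1e-8))
    stop("censored records must sit exactly at the censoring limit")
  if (!all(records$male %in% c(0, 1)))
    stop("`male` must be coded 0/1")
  records
}

# Keep only each participant's first record (the first delay-task exposure is
# the psychologically meaningful one; later exposures are dropped).
first_records <- function(records) {
  dup <- duplicated(records$participant_id)
  if (any(dup)) {
    warning(sum(dup), " duplicate participant id(s); keeping earliest record")
    records <- records[!dup, , drop = FALSE]
  }
  records
}

# Precompute everything the likelihood needs.
tobit_data <- function(records, censor_seconds) {
  records <- validate_wait_records(records, censor_seconds)
  g <- as.integer(factor(records$condition))
  list(
    y = log(pmax(records$wait_seconds, 1)),
    d = as.logical(records$censored),
    age = as.numeric(records$age_months),
    male = as.numeric(records$male),
    g = g,
    G = max(g),
    cond_levels = levels(factor(records$condition)),
    lc = log(censor_seconds),
    n = nrow(records)
  )
}

# inverse Mills ratio phi(a) / (1 - Phi(a)), stable in both tails
mills <- function(a) {
  exp(stats::dnorm(a, log = TRUE) -
        stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
}

# ---- internal: marginal likelihood by adaptive Gauss-Hermite ----------------

# Per-condition log integrand pieces. Given a G x K matrix of eta values,
# returns the G x K matrix of conditional log-likelihood sums
# sum_{i in g} log f(y_i | eta).
cond_loglik_mat <- function(dat, mu, eta_mat, sigma_eps) {
  K <- ncol(eta_mat)
  lin <- mu + eta_mat[dat$g, , drop = FALSE]     # n x K
  ll <- matrix(0, dat$n, K)
  if (any(!dat$d)) {
    u <- !dat$d
    ll[u, ] <- stats::dnorm(dat$y[u], lin[u, , drop = FALSE], sigma_eps,
                            log = TRUE)
  }
  if (any(dat$d)) {
    a <- (dat$lc - lin[dat$d, , drop = FALSE]) / sigma_eps
    ll[dat$d, ] <- stats::pnorm(a, lower.tail = FALSE, log.p = TRUE)
  }
  rowsum(ll, dat$g)
}

# Posterior mode and curvature of eta_g given parameters, by damped Newton.
# The per-condition log posterior is strictly concave in eta.
eta_mode <- function(dat, mu, sigma_eta, sigma_eps, tol = 1e-10,
                     max_iter = 50L) {
  eta <- numeric(dat$G)
  se2 <- sigma_eps^2
  for (it in seq_len(max_iter)) {
    lin <- mu + eta[dat$g]
    gr_obs <- numeric(dat$n)
    hs_obs <- numeric(dat$n)
    if (any(!dat$d)) {
      u <- !dat$d
      z <- (dat$y[u] - lin[u]) / sigma_eps
      gr_obs[u] <- z / sigma_eps
      hs_obs[u] <- -1 / se2
    }
    if (any(dat$d)) {
      a <- (dat$lc - lin[dat$d]) / sigma_eps
      lam <- mills(a)
      gr_obs[dat$d] <- lam / sigma_eps
      hs_obs[dat$d] <- -lam * (lam - a) / se2
    }
    gr <- rowsum(gr_obs, dat$g)[, 1] - eta / sigma_eta^2
    hs <- rowsum(hs_obs, dat$g)[, 1] - 1 / sigma_eta^2
    step <- -gr / hs
    step <- pmin(pmax(step, -5), 5)
    eta <- eta + step
    if (max(abs(step)) < tol) break
  }
  list(mode = eta, scale = 1 / sqrt(-hs))
}

# Log marginal likelihood contributions per condition plus the quadrature
# grid used (nodes and normalized posterior log-weights), for reuse by the
# empirical-Bayes predictor.
tobit_marginal <- function(dat, theta, gh) {
  alpha <- theta[1L]; b_age <- theta[2L]; b_male <- theta[3L]
  sigma_eta <- exp(theta[4L]); sigma_eps <- exp(theta[5L])
  mu <- alpha + b_age * dat$age + b_male * dat$male
  mo <- eta_mode(dat, mu, sigma_eta, sigma_eps)
  K <- length(gh$x)
  # adaptive grid: eta_gk = mode_g + sqrt(2) * scale_g * x_k
  eta_mat <- mo$mode + sqrt(2) * mo$scale %o% gh$x          # G x K
  h <- cond_loglik_mat(dat, mu, eta_mat, sigma_eps) +
    stats::dnorm(eta_mat, 0, sigma_eta, log = TRUE)
  lt <- sweep(h, 2L, log(gh$w) + gh$x^2, `+`) +
    log(sqrt(2) * mo$scale)
  m0 <- apply(lt, 1L, max)
  logL <- m0 + log(rowSums(exp(lt - m0)))
  list(logL = logL, eta_mat = eta_mat, log_w = lt - logL, mu = mu,
       sigma_eta = sigma_eta, sigma_eps = sigma_eps)
}

tobit_negloglik <- function(theta, dat, gh) {
  -sum(tobit_marginal(dat, theta, gh)$logL)
}

# ---- fitting ----------------------------------------------------------------

#' Fit a random-effects tobit model to censored log wait times
#'
#' Maximum-likelihood estimation of
#' \deqn{y^*_{gi} = \alpha + \beta_1 \mathrm{age}_{gi} + \beta_2
#'   \mathrm{male}_{gi} + \eta_g + \varepsilon_{gi},}
#' where \eqn{y^*} is the latent log wait time, \eqn{\eta_g \sim N(0,
#' \sigma_\eta^2)} is an experimental-condition random effect and
#' \eqn{\varepsilon_{gi} \sim N(0, \sigma_\varepsilon^2)} an individual
#' error. Observed waits are right-censored at `censor_seconds`: censored
#' records contribute the upper-tail probability, uncensored records the
#' normal density, to the conditional likelihood. The condition effect is
#' integrated out by adaptive Gauss-Hermite quadrature (nodes centred and
#' scaled at the per-condition posterior mode, found by Newton iteration on
#' the strictly concave log posterior). Standard errors come from the
#' observed information (numerical Hessian at the optimum, delta method for
#' the standard deviations, which are estimated on the log scale).
#'
#' Optimization runs from `multistart` deterministic perturbations of a
#' moments-based starting point and keeps the best optimum, guarding against
#' local maxima without introducing randomness: the fit is a deterministic
#' function of the data.
#'
#' Only each participant's first delay-task record enters the fit; duplicate
#' participant ids are dropped with a warning. Wait times of 0 s are floored
#' at 1 s before logging.
#'
#' @param records data frame with columns `participant_id`, `condition`,
#'   `age_months`, `male` (0/1), `wait_seconds`, `censored` (logical).
#' @param censor_seconds censoring limit in seconds (default 900, i.e. 15
#'   minutes).
#' @param n_quad number of Gauss-Hermite nodes (default 21).
#' @param multistart number of deterministic starting points (default 3).
#' @param control list passed to [stats::nlminb()] `control`.
#' @return an object of class `"tobit_re_fit"`: list with `coefficients`
#'   (`alpha`, `beta_age`, `beta_male`), `sigma_eta`, `sigma_eps`, `se`
#'   (all five parameters), `loglik`, `eb` (data frame of per-condition
#'   empirical-Bayes posterior means of \eqn{\eta_g}), `vcov_theta`,
#'   `convergence`, sample sizes, and the censoring limit.
#' @examples
#' spec <- cohort_spec(n_participants = 120, n_conditions = 6,
#'                     condition_sizes = rep(20, 6), seed = 1)
#' coh <- generate_cohort(spec)
#' fit <- fit_tobit_re(coh$wait_records)
#' fit
#' @export
fit_tobit_re <- function(records, censor_seconds = 900, n_quad = 21L,
                         multistart = 3L, control = list()) {
  records <- first_records(records)
  dat <- tobit_data(records, censor_seconds)
  if (dat$G < 2L)
    stop("sigma_eta is not identified with a single condition")
  if (all(dat$d))
    stop("all observations censored: no interior optimum")
  if (dat$n < 10L)
    stop("too few records to fit the model")
  gh <- pracma::gaussHermite(n_quad)

  # moments-based start: OLS treating censored waits as exact
  X <- cbind(1, dat$age, dat$male)
  ols <- stats::lm.fit(X, dat$y)
  r <- ols$residuals
  eta0 <- tapply(r, dat$g, mean)
  s_eta0 <- max(stats::sd(eta0), 0.1)
  s_eps0 <- max(stats::sd(r) * 1.2, 0.2)
  theta0 <- c(ols$coefficients, log(s_eta0), log(s_eps0))
  names(theta0) <- c("alpha", "beta_age", "beta_male",
                     "log_sigma_eta", "log_sigma_eps")
  perturb <- list(
    c(0, 0, 0, 0, 0),
    c(0.5, 0, 0, 0.4, -0.3),
    c(-0.5, 0, 0, -0.4, 0.3)
  )[seq_len(max(1L, multistart))]

  ctrl <- utils::modifyList(list(rel.tol = 1e-10, iter.max = 500L,
                                 eval.max = 1000L), control)
  lower <- c(-Inf, -Inf, -Inf, -12, -8)
  upper <- c(Inf, Inf, Inf, 5, 5)
  fits <- lapply(perturb, function(p) {
    stats::nlminb(theta0 + p, tobit_negloglik, dat = dat, gh = gh,
                  lower = lower, upper = upper, control = ctrl)
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  if (!best$convergence %in% c(0L, 1L) ||
      !is.finite(best$objective))
    stop("tobit random-effects fit did not converge: ", best$message)
  theta <- best$par
  if (theta[5L] >= upper[5L] - 1e-6 || theta[1L] > 50)
    stop("estimation ran to the boundary: no interior optimum")

  H <- stats::optimHess(theta, tobit_negloglik, dat = dat, gh = gh)
  vcov_theta <- tryCatch(solve(H), error = function(e) {
    warning("observed information is singular; standard errors unavailable")
    matrix(NA_real_, 5, 5)
  })
  se_theta <- sqrt(pmax(diag(vcov_theta), 0))
  sigma_eta <- exp(theta[4L]); sigma_eps <- exp(theta[5L])
  se <- c(se_theta[1:3], sigma_eta * se_theta[4L], sigma_eps * se_theta[5L])
  names(se) <- c("alpha", "beta_age", "beta_male", "sigma_eta", "sigma_eps")

  marg <- tobit_marginal(dat, theta, gh)
  w_post <- exp(marg$log_w)
  eb_eta <- rowSums(w_post * marg$eta_mat)
  eb <- data.frame(
    condition = dat$cond_levels,
    n = as.integer(tabulate(dat$g, dat$G)),
    n_censored = as.integer(rowsum(as.numeric(dat$d), dat$g)[, 1]),
    eb_eta = unname(eb_eta),
    stringsAsFactors = FALSE
  )

  structure(list(
    coefficients = c(alpha = unname(theta[1L]), beta_age = unname(theta[2L]),
                     beta_male = unname(theta[3L])),
    sigma_eta = unname(sigma_eta),
    sigma_eps = unname(sigma_eps),
    se = se,
    loglik = -best$objective,
    eb = eb,
    eb_quad = list(eta_mat = marg$eta_mat, log_w = marg$log_w),
    vcov_theta = vcov_theta,
    convergence = list(code = best$convergence, message = best$message,
                       n_starts = length(perturb)),
    n = dat$n,
    n_censored = sum(dat$d),
    n_conditions = dat$G,
    censor_seconds = censor_seconds,
    n_quad = n_quad,
    call = match.call()
  ), class = "tobit_re_fit")
}

#' @export
print.tobit_re_fit <- function(x, digits = 3, ...) {
  cat("Random-effects tobit model of log wait time",
      sprintf("(censored at %g s)\n", x$censor_seconds))
  est <- c(x$coefficients, sigma_eta = x$sigma_eta, sigma_eps = x$sigma_eps)
  lab <- c("Age at delay task (months)", "Male", "Constant",
           "SD of condition random effect", "SD of individual error")
  ord <- c("beta_age", "beta_male", "alpha", "sigma_eta", "sigma_eps")
  tab <- data.frame(
    estimate = round(est[ord], digits),
    se = round(x$se[ord], digits),
    row.names = lab
  )
  print(tab, ...)
  cat(sprintf("N = %d (%d censored), %d conditions, logLik = %.2f\n",
              x$n, x$n_censored, x$n_conditions, x$loglik))
  invisible(x)
}

#' @export
coef.tobit_re_fit <- function(object, ...) {
  c(object$coefficients, sigma_eta = object$sigma_eta,
    sigma_eps = object$sigma_eps)
}

#' @export
logLik.tobit_re_fit <- function(object, ...) {
  structure(object$loglik, df = 5L, nobs = object$n, class = "logLik")
}

# ---- prediction -------------------------------------------------------------

#' Empirical-Bayes expected log wait time
#'
#' Returns \eqn{\hat\alpha + \hat\beta_1 \mathrm{age} + \hat\beta_2
#' \mathrm{male} + \hat\eta_g}, where \eqn{\hat\eta_g} is the posterior mean
#' of the condition random effect given the fitted data, treating the
#' maximum-likelihood parameter estimates as the true parameter values. The
#' posterior mean shrinks raw condition deviations toward zero, more so for
#' small conditions.
#'
#' @param fit a [fit_tobit_re()] object.
#' @param records data frame with columns `condition`, `age_months`, `male`.
#' @return numeric vector of expected log wait times (log-seconds).
#' @export
expected_ln_wait <- function(fit, records) {
  stopifnot(inherits(fit, "tobit_re_fit"))
  idx <- match(as.character(records$condition), fit$eb$condition)
  if (anyNA(idx))
    stop("unknown condition(s): ",
         paste(unique(records$condition[is.na(idx)]), collapse = ", "))
  b <- fit$coefficients
  unname(b["alpha"] + b["beta_age"] * records$age_months +
           b["beta_male"] * records$male + fit$eb$eb_eta[idx])
}

#' Impute the latent log wait time for censored records
#'
#' For a participant who was still waiting at the censoring limit, estimates
#' \eqn{E[y^* \mid y^* \ge \ln C, \mathrm{age}, \mathrm{male}, g]} by Monte
#' Carlo with `n_draws` draws, treating the fitted parameters as the truth.
#' The default (`eta = "point"`) conditions on the empirical-Bayes point
#' estimate of the condition effect and draws the individual residual from
#' its truncated normal distribution; `eta = "posterior"` additionally draws
#' the condition effect from its (censoring-reweighted) posterior before
#' drawing the residual. Results always exceed the log censoring limit.
#'
#' @param fit a [fit_tobit_re()] object.
#' @param records data frame of censored records (columns `condition`,
#'   `age_months`, `male`, `censored`); calling this on uncensored records
#'   is an error.
#' @param n_draws Monte Carlo draws per record (default 10000).
#' @param seed optional integer seed for the draws.
#' @param eta `"point"` or `"posterior"`, see Details.
#' @return numeric vector of imputed log wait times (log-seconds).
#' @export
impute_censored_ln_wait <- function(fit, records, n_draws = 10000L,
                                    seed = NULL,
                                    eta = c("point", "posterior")) {
  stopifnot(inherits(fit, "tobit_re_fit"))
  eta <- match.arg(eta)
  if (!all(records$censored))
    stop("impute_censored_ln_wait() called on uncensored record(s)")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  lc <- log(fit$censor_seconds)
  s <- fit$sigma_eps
  mu <- expected_ln_wait(fit, records)
  if (eta == "point") {
    vapply(mu, function(m) {
      a <- (lc - m) / s
      u <- stats::runif(n_draws, stats::pnorm(a), 1)
      mean(m + s * stats::qnorm(u))
    }, numeric(1))
  } else {
    b <- fit$coefficients
    fixed <- unname(b["alpha"] + b["beta_age"] * records$age_months +
                      b["beta_male"] * records$male)
    gi <- match(as.character(records$condition), fit$eb$condition)
    vapply(seq_along(gi), function(j) {
      nodes <- fit$eb_quad$eta_mat[gi[j], ]
      lw <- fit$eb_quad$log_w[gi[j], ] +
        stats::pnorm((lc - fixed[j] - nodes) / s, lower.tail = FALSE,
                     log.p = TRUE)
      w <- exp(lw - max(lw)); w <- w / sum(w)
      k <- sample.int(length(nodes), n_draws, replace = TRUE, prob = w)
      m <- fixed[j] + nodes[k]
      u <- stats::runif(n_draws, stats::pnorm((lc - m) / s), 1)
      mean(m + s * stats::qnorm(u))
    }, numeric(1))
  }
}

#' Rank-normalized delay (RND) scores
#'
#' Three steps: (a) the fitted model supplies an expected log wait time for
#' each participant's condition, age and sex; (b) the deviation between the
#' participant's actual log wait time (or, for censored participants, the
#' simulated conditional expectation of the latent log wait) and that
#' expectation is computed; (c) deviations are rank-normalized within the
#' analysis sample.
#'
#' @param records wait-record data frame (one row per participant; duplicate
#'   ids are reduced to the first record with a warning).
#' @param fit a converged [fit_tobit_re()] object.
#' @param n_draws,seed passed to [impute_censored_ln_wait()].
#' @param eta imputation mode, see [impute_censored_ln_wait()].
#' @return data frame with `participant_id`, `condition`, `deviation`
#'   (log-seconds) and `rnd` (standard-normal score).
#' @export
compute_rnd <- function(records, fit, n_draws = 10000L, seed = NULL,
                        eta = c("point", "posterior")) {
  stopifnot(inherits(fit, "tobit_re_fit"))
  eta <- match.arg(eta)
  records <- first_records(records)
  records <- validate_wait_records(records, fit$censor_seconds)
  y <- log(pmax(records$wait_seconds, 1))
  cen <- as.logical(records$censored)
  if (any(cen))
    y[cen] <- impute_censored_ln_wait(fit, records[cen, , drop = FALSE],
                                      n_draws = n_draws, seed = seed,
                                      eta = eta)
  deviation <- y - expected_ln_wait(fit, records)
  data.frame(
    participant_id = records$participant_id,
    condition = records$condition,
    deviation = deviation,
    rnd = rank_inverse_normal(deviation),
    stringsAsFactors = FALSE
  )
}

#' Evaluate the wait-time model at fixed parameters
#'
#' Builds a `"tobit_re_fit"` object from known parameter values instead of
#' estimating them: empirical-Bayes condition effects and the marginal
#' log-likelihood are computed from the data at the supplied parameters,
#' and standard errors are `NA`. Useful in simulation studies where the
#' generating parameters are known and re-estimating them on every
#' replicate is not the question, and as the oracle arm of estimation
#' checks.
#'
#' @param records wait-record data frame (see [fit_tobit_re()]).
#' @param params a [tobit_params()] object.
#' @param n_quad Gauss-Hermite nodes.
#' @return a `"tobit_re_fit"` object (with `convergence$code = NA`).
#' @export
tobit_fit_fixed <- function(records, params, n_quad = 21L) {
  stopifnot(inherits(params, "tobit_params"))
  records <- first_records(records)
  dat <- tobit_data(records, params$censor_seconds)
  gh <- pracma::gaussHermite(n_quad)
  theta <- c(params$alpha, params$beta_age, params$beta_male,
             log(params$sigma_eta), log(params$sigma_eps))
  marg <- tobit_marginal(dat, theta, gh)
  w_post <- exp(marg$log_w)
  eb <- data.frame(
    condition = dat$cond_levels,
    n = as.integer(tabulate(dat$g, dat$G)),
    n_censored = as.integer(rowsum(as.numeric(dat$d), dat$g)[, 1]),
    eb_eta = unname(rowSums(w_post * marg$eta_mat)),
    stringsAsFactors = FALSE
  )
  structure(list(
    coefficients = c(alpha = params$alpha, beta_age = params$beta_age,
                     beta_male = params$beta_male),
    sigma_eta = params$sigma_eta,
    sigma_eps = params$sigma_eps,
    se = stats::setNames(rep(NA_real_, 5),
                         c("alpha", "beta_age", "beta_male", "sigma_eta",
                           "sigma_eps")),
    loglik = sum(marg$logL),
    eb = eb,
    eb_quad = list(eta_mat = marg$eta_mat, log_w = marg$log_w),
    vcov_theta = matrix(NA_real_, 5, 5),
    convergence = list(code = NA_integer_, message = "fixed parameters",
                       n_starts = 0L),
    n = dat$n,
    n_censored = sum(dat$d),
    n_conditions = dat$G,
    censor_seconds = params$censor_seconds,
    n_quad = n_quad,
    call = match.call()
  ), class = "tobit_re_fit")
}
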