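# Default per-condition sample sizes: 21 conditions spanning 3 to 165
# participants and summing to 543, mirroring the design imbalance of the
# original wait-task experiments (per-condition sizes were reported only as
# a 3-165 range; this allocation is a modelling choice).
default_condition_sizes <- function() {
  c(3, 4, 5, 6, 7, 8, 10, 12, 14, 16, 18, 20, 22, 24, 26, 28, 30, 35, 40,
    50, 165)
}

# Conditions treated as "diagnostic" (exposed rewards, spontaneous ideation)
# by default: 6 of the 21, jointly covering ~30% of participants (164/543),
# so that a ~113-participant survey subsample contains ~34 diagnostic
# participants.
default_diagnostic_conditions <- function() c(6L, 9L, 13L, 17L, 19L, 20L)

#' Parameters of the random-effects tobit wait-time model
#'
#' Container for the five model parameters plus the censoring limit. The
#' defaults are the estimates obtained on the full preschool cohort
#' (n = 543, 21 experimental conditions) and define the data-generating
#' conditions the synthetic cohort emulates.
#'
#' @param alpha intercept, log-seconds.
#' @param beta_age effect of one month of age, log-seconds.
#' @param beta_male effect of being male, log-seconds.
#' @param sigma_eta SD of the condition-level random effect (log-seconds).
#' @param sigma_eps SD of the individual-specific error (log-seconds).
#' @param censor_seconds censoring limit of the wait task, seconds.
#' @return a list of class `"tobit_params"`.
#' @export
tobit_params <- function(alpha = 2.289, beta_age = 0.081, beta_male = -0.673,
                         sigma_eta = 0.786, sigma_eps = 2.469,
                         censor_seconds = 900) {
  stopifnot(sigma_eta >= 0, sigma_eps > 0, censor_seconds > 0)
  structure(list(alpha = alpha, beta_age = beta_age, beta_male = beta_male,
                 sigma_eta = sigma_eta, sigma_eps = sigma_eps,
                 censor_seconds = censor_seconds),
            class = "tobit_params")
}

# Outcome battery definition: 11 mid-life capital formation measures.
# Loadings are on the latent self-regulation factor; `reverse` marks
# variables recorded in the unfavourable direction (generated and stored on
# that raw scale, so the indices stage must reverse them); `n_missing` is
# the number of survey participants with the outcome missing (MCAR),
# matching the per-outcome analysis Ns of the published battery.
default_outcome_spec <- function(loading = 0.212) {
  data.frame(
    name = c("net_worth", "permanent_income", "wealth_income_ratio",
             "high_interest_debt", "credit_card_misuse", "delay_choice",
             "savings_rate", "financial_health", "education_years",
             "forward_looking", "social_status"),
    loading = loading,
    reverse = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE,
                FALSE, FALSE, FALSE),
    n_missing = c(4L, 1L, 4L, 4L, 0L, 1L, 7L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
}

# CCQ-style item battery definition: item counts per assessment age
# (23 at age 17, 31 at ages 27 and 37; together with the preschool delay
# score the composite index has 86 components). A quarter of the items are
# negatively keyed.
default_item_spec <- function(loading = 0.4) {
  list(ages = c(17L, 27L, 37L), n_items = c(23L, 31L, 31L),
       loading = loading)
}

ccq_item_names <- function(age, n_items) {
  sprintf("ccq%d_item%02d", age, seq_len(n_items))
}

ccq_item_signs <- function(n_items) {
  rep(c(1, 1, 1, -1), length.out = n_items)
}

#' Default CCQ subscale definitions
#'
#' Six subscales per assessment age: "delay of gratification" and "general
#' cognitive ability" (3 items each) plus four factors ("attention",
#' "coping", "goal pursuit", "concern for others") splitting the remaining
#' items as evenly as possible. Item ids follow the synthetic generator's
#' naming; real data in the same schema can supply its own definitions,
#' since subscale membership is configuration, not code.
#'
#' @param age assessment age (17, 27 or 37).
#' @param n_items number of items in the battery at that age.
#' @return list of six subscale definitions, each with `name`, `items`
#'   (item ids) and `signs` (+1/-1 per item).
#' @export
default_ccq_subscales <- function(age, n_items) {
  items <- ccq_item_names(age, n_items)
  signs <- ccq_item_signs(n_items)
  sizes <- c(3L, 3L)
  rest <- n_items - 6L
  base <- rest %/% 4L
  sizes <- c(sizes, base + as.integer(seq_len(4L) <= rest %% 4L))
  nm <- c("delay_of_gratification", "general_cognitive_ability",
          "attention", "coping", "goal_pursuit", "concern_for_others")
  idx <- split(seq_len(n_items), rep(seq_along(sizes), sizes))
  lapply(seq_along(sizes), function(s) {
    list(name = nm[s], items = items[idx[[s]]], signs = signs[idx[[s]]])
  })
}

#' Specification of a synthetic cohort
#'
#' Defines the data-generating conditions for [generate_cohort()]: cohort
#' and survey sizes, the condition structure and tobit parameters of the
#' wait task, the share of individual log-wait variance carried by the
#' latent self-regulation factor, the item battery and outcome loadings,
#' and missingness. Defaults reproduce the study conditions the analysis
#' assumes: 543 participants in 21 conditions with log-normal wait times
#' censored at 900 s, a 113-participant mid-life survey subsample, and
#' loadings calibrated so that the estimated composite-index battery
#' correlations average about 0.19 and the preschool-delay battery
#' correlations about 0.02.
#'
#' @param n_participants cohort size.
#' @param n_conditions number of experimental conditions.
#' @param condition_sizes integer vector summing to `n_participants`;
#'   `NULL` uses [default_condition_sizes()] for the default geometry, or
#'   a near-equal split otherwise.
#' @param n_survey size of the mid-life survey subsample (drawn completely
#'   at random from the cohort).
#' @param tobit a [tobit_params()] object.
#' @param latent_loading_wait share (0-1) of individual log-wait error
#'   variance attributable to the latent self-regulation factor.
#' @param item_spec list with `ages`, `n_items`, `loading`
#'   (see [default_item_spec()]).
#' @param outcome_spec data frame as in [default_outcome_spec()].
#' @param ccq_missing_rate probability a survey participant is missing the
#'   entire item battery (all ages).
#' @param age_mean,age_sd,age_range age-at-task distribution in months
#'   (normal, truncated to `age_range`).
#' @param p_male probability of being male.
#' @param diagnostic_conditions indices of conditions flagged diagnostic.
#' @param diagnostic_boost multiplier (>= 1) applied to
#'   `latent_loading_wait` within diagnostic conditions; the default 1
#'   leaves the loading homogeneous, values above 1 emulate the hypothesis
#'   that only diagnostic task variants reveal self-regulatory competence.
#' @param seed integer seed; a fixed seed makes [generate_cohort()] output
#'   byte-identical across calls.
#' @return a list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_participants = 543L,
                        n_conditions = 21L,
                        condition_sizes = NULL,
                        n_survey = 113L,
                        tobit = tobit_params(),
                        latent_loading_wait = 0.0113,
                        item_spec = default_item_spec(),
                        outcome_spec = default_outcome_spec(),
                        ccq_missing_rate = 3 / 113,
                        age_mean = 52.1, age_sd = 5.7,
                        age_range = c(24, 72),
                        p_male = 0.48,
                        diagnostic_conditions = NULL,
                        diagnostic_boost = 1,
                        seed = 1L) {
  if (is.null(condition_sizes)) {
    if (n_participants == 543L && n_conditions == 21L) {
      condition_sizes <- default_condition_sizes()
    } else {
      base <- n_participants %/% n_conditions
      condition_sizes <- rep(base, n_conditions) +
        as.integer(seq_len(n_conditions) <= n_participants %% n_conditions)
    }
  }
  if (length(condition_sizes) != n_conditions ||
      sum(condition_sizes) != n_participants)
    stop("configuration error: condition_sizes must have length ",
         n_conditions, " and sum to ", n_participants)
  if (latent_loading_wait < 0 || latent_loading_wait > 1)
    stop("latent_loading_wait must be in [0, 1]")
  if (any(outcome_spec$loading < 0 | outcome_spec$loading > 1))
    stop("outcome loadings must be in [0, 1]")
  if (item_spec$loading < 0 || item_spec$loading > 1)
    stop("item loading must be in [0, 1]")
  if (n_survey > n_participants)
    stop("n_survey cannot exceed n_participants")
  if (is.null(diagnostic_conditions)) {
    diagnostic_conditions <-
      if (n_participants == 543L && n_conditions == 21L)
        default_diagnostic_conditions()
      else
        seq_len(max(1L, round(n_conditions * 6 / 21)))
  }
  stopifnot(all(diagnostic_conditions %in% seq_len(n_conditions)),
            diagnostic_boost >= 1)
  structure(list(
    n_participants = as.integer(n_participants),
    n_conditions = as.integer(n_conditions),
    condition_sizes = as.integer(condition_sizes),
    n_survey = as.integer(n_survey),
    tobit = tobit,
    latent_loading_wait = latent_loading_wait,
    item_spec = item_spec,
    outcome_spec = outcome_spec,
    ccq_missing_rate = ccq_missing_rate,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    p_male = p_male,
    diagnostic_conditions = as.integer(diagnostic_conditions),
    diagnostic_boost = diagnostic_boost,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# truncated-normal draws by rejection (the truncation is mild: 24-72 months
# around a mean of ~52 with SD ~5.7)
rtruncnorm_simple <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws a complete cohort under the generative model the analysis assumes:
#' a per-participant latent self-regulation factor \eqn{L \sim N(0,1)};
#' latent log wait times \eqn{y^* = \alpha + \beta_1 \mathrm{age} + \beta_2
#' \mathrm{male} + \eta_g + \varepsilon} with condition effects
#' \eqn{\eta_g \sim N(0, \sigma_\eta^2)} and individual errors decomposed
#' into a latent-factor share (`latent_loading_wait`) and noise; observed
#' waits censored at the task limit; CCQ-style item ratings
#' \eqn{s_j (a L + \sqrt{1-a^2}\, e)} with item keying \eqn{s_j = \pm 1};
#' and 11 outcome variables \eqn{b_k L + \sqrt{1-b_k^2}\, e} observed on a
#' survey subsample with per-outcome missing-completely-at-random
#' missingness. Reverse-flagged outcomes are stored on the unfavourable raw
#' scale (negated), so downstream index construction must apply
#' [reverse_scale()].
#'
#' One global seed fans out to fixed per-component substreams, so any
#' component can be regenerated independently and a fixed seed yields
#' byte-identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `"synthetic_cohort"` with elements `participants`
#'   (id, condition, age, sex, latent factor, diagnostic and survey flags),
#'   `wait_records` (one record per participant, schema of
#'   [fit_tobit_re()]), `ccq` (list of participant-by-item rating matrices,
#'   one per assessment age, survey subsample only), `outcomes` (data frame,
#'   survey subsample only, `NA` for missing), and the `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  tp <- spec$tobit
  sub <- function(k) set.seed(spec$seed * 97L + k)

  # structure: condition assignment, age, sex
  sub(1L)
  cond <- rep(seq_len(spec$n_conditions), spec$condition_sizes)
  cond_id <- sprintf("C%02d", cond)
  age <- rtruncnorm_simple(n, spec$age_mean, spec$age_sd,
                           spec$age_range[1], spec$age_range[2])
  male <- stats::rbinom(n, 1L, spec$p_male)
  pid <- sprintf("P%04d", seq_len(n))
  diagnostic <- cond %in% spec$diagnostic_conditions

  # latent self-regulation factor
  sub(2L)
  latent <- stats::rnorm(n)

  # wait times
  sub(3L)
  eta_g <- stats::rnorm(spec$n_conditions, 0, tp$sigma_eta)
  lam <- rep(spec$latent_loading_wait, n)
  lam[diagnostic] <- pmin(lam[diagnostic] * spec$diagnostic_boost, 1)
  eps <- sqrt(lam) * tp$sigma_eps * latent +
    sqrt(1 - lam) * tp$sigma_eps * stats::rnorm(n)
  ystar <- tp$alpha + tp$beta_age * age + tp$beta_male * male +
    eta_g[cond] + eps
  censored <- ystar >= log(tp$censor_seconds)
  wait <- pmin(exp(ystar), tp$censor_seconds)

  # survey subsample
  sub(7L)
  survey <- logical(n)
  survey[sample.int(n, spec$n_survey)] <- TRUE

  # item batteries (survey subsample only)
  sub(4L)
  a <- spec$item_spec$loading
  spid <- pid[survey]
  ccq <- vector("list", length(spec$item_spec$ages))
  names(ccq) <- paste0("age", spec$item_spec$ages)
  for (j in seq_along(spec$item_spec$ages)) {
    m <- spec$item_spec$n_items[j]
    sg <- ccq_item_signs(m)
    noise <- matrix(stats::rnorm(length(spid) * m), length(spid), m)
    core <- a * latent[survey] + sqrt(1 - a^2) * noise
    ratings <- sweep(core, 2L, sg, `*`)
    dimnames(ratings) <- list(spid,
                              ccq_item_names(spec$item_spec$ages[j], m))
    ccq[[j]] <- ratings
  }

  # outcomes (survey subsample only)
  sub(5L)
  os <- spec$outcome_spec
  out <- matrix(NA_real_, length(spid), nrow(os),
                dimnames = list(spid, os$name))
  for (k in seq_len(nrow(os))) {
    b <- os$loading[k]
    v <- b * latent[survey] + sqrt(1 - b^2) * stats::rnorm(length(spid))
    if (os$reverse[k]) v <- -v
    out[, k] <- v
  }

  # missingness: exact per-outcome MCAR counts, plus whole-battery CCQ
  # non-response at the participant level
  sub(6L)
  for (k in seq_len(nrow(os))) {
    if (os$n_missing[k] > 0L)
      out[sample.int(length(spid), os$n_missing[k]), k] <- NA_real_
  }
  ccq_miss <- stats::runif(length(spid)) < spec$ccq_missing_rate
  for (j in seq_along(ccq)) ccq[[j]][ccq_miss, ] <- NA_real_

  participants <- data.frame(
    participant_id = pid, condition = cond_id, age_months = age,
    male = male, latent = latent, diagnostic = diagnostic, survey = survey,
    stringsAsFactors = FALSE
  )
  wait_records <- data.frame(
    participant_id = pid, condition = cond_id, age_months = age,
    male = male, wait_seconds = wait, censored = censored,
    stringsAsFactors = FALSE
  )
  structure(list(
    participants = participants,
    wait_records = wait_records,
    ccq = ccq,
    outcomes = data.frame(participant_id = spid, out,
                          stringsAsFactors = FALSE, row.names = NULL),
    spec = spec
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d participants, %d conditions, %d surveyed\n",
    nrow(x$participants), x$spec$n_conditions, sum(x$participants$survey)))
  cat(sprintf("  censored wait times: %d (%.1f%%)\n",
              sum(x$wait_records$censored),
              100 * mean(x$wait_records$censored)))
  invisible(x)
}

#' Write a synthetic cohort to delimited text files
#'
#' Writes four files to `dir`: `wait_records.tsv` (one row per participant:
#' id, condition, age in months, male indicator, wait seconds, censoring
#' flag), `ccq_items.tsv` (long format: id, assessment age, item id,
#' rating), `outcomes.tsv` (wide format, `NA` for missing), and
#' `metadata.json` echoing the generating specification (schema version
#' included). [read_cohort()] reads them back.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wr(cohort$wait_records, "wait_records.tsv")
  long <- do.call(rbind, lapply(seq_along(cohort$ccq), function(j) {
    m <- cohort$ccq[[j]]
    data.frame(
      participant_id = rep(rownames(m), ncol(m)),
      age = cohort$spec$item_spec$ages[j],
      item = rep(colnames(m), each = nrow(m)),
      rating = as.vector(m),
      stringsAsFactors = FALSE
    )
  }))
  wr(long[!is.na(long$rating), ], "ccq_items.tsv")
  wr(cohort$outcomes, "outcomes.tsv")
  meta <- unclass(cohort$spec)
  meta$tobit <- unclass(meta$tobit)
  jsonlite::write_json(
    list(schema_version = "1.0", spec = meta),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `wait_records.tsv`, `ccq_items.tsv`,
#'   `outcomes.tsv` and `metadata.json`.
#' @return list with `wait_records`, `ccq` (matrices per age), `outcomes`
#'   and `meta` (parsed metadata).
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.table(file.path(dir, f), sep = "\t",
                                      header = TRUE,
                                      stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  long <- rd("ccq_items.tsv")
  outcomes <- rd("outcomes.tsv")
  ages <- sort(unique(long$age))
  ccq <- lapply(ages, function(a) {
    sub <- long[long$age == a, ]
    items <- sort(unique(sub$item))
    m <- matrix(NA_real_, nrow(outcomes), length(items),
                dimnames = list(outcomes$participant_id, items))
    m[cbind(match(sub$participant_id, rownames(m)),
            match(sub$item, items))] <- sub$rating
    m
  })
  names(ccq) <- paste0("age", ages)
  list(wait_records = rd("wait_records.tsv"), ccq = ccq,
       outcomes = outcomes, meta = meta)
}
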