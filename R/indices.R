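#' Annual high-interest debt burden
#'
#' For each debt category, the dollar amount of debt is multiplied by the
#' part of its interest rate exceeding the threshold (default 6%/year), with
#' the rate taken as the midpoint of the reported rate bucket; categories at
#' or below the threshold contribute nothing. The result (summed across
#' categories) is the annual interest paid above the threshold, in dollars
#' per year; it enters the outcome battery reverse-scaled.
#'
#' @param debt_amounts dollar amounts per category (non-negative).
#' @param rate_bucket_midpoints interest-rate midpoints per category, as
#'   fractions (0.15 = 15%/year).
#' @param threshold rate threshold as a fraction (default 0.06).
#' @return dollars per year of interest above the threshold.
#' @examples
#' high_interest_debt(10000, 0.15)              # 900
#' high_interest_debt(c(5000, 2000), c(0.20, 0.04))  # 700
#' @export
high_interest_debt <- function(debt_amounts, rate_bucket_midpoints,
                               threshold = 0.06) {
  if (length(debt_amounts) != length(rate_bucket_midpoints))
    stop("amounts and rate midpoints must have the same length")
  if (any(debt_amounts < 0, na.rm = TRUE))
    stop("validation error: negative debt amount")
  if (any(rate_bucket_midpoints < 0, na.rm = TRUE))
    stop("validation error: negative interest rate")
  sum(debt_amounts * pmax(rate_bucket_midpoints - threshold, 0))
}

#' Permanent income
#'
#' Mean of household income at two time points divided by the number of
#' adults in the household. Any inflation adjustment between the two income
#' years is the caller's responsibility (supply already-adjusted dollars).
#'
#' @param income_year1,income_year2 household income at the two reference
#'   years, same units.
#' @param n_adults number of adults in the household (>= 1).
#' @return income per adult.
#' @export
permanent_income <- function(income_year1, income_year2, n_adults) {
  if (any(n_adults < 1, na.rm = TRUE))
    stop("n_adults must be at least 1")
  (income_year1 + income_year2) / 2 / n_adults
}

#' Equal-weighted rank-normalized index
#'
#' Rank-normalizes each component, averages them for every participant with
#' at least `min_present` components observed, and rank-normalizes the
#' average. This is the construction behind the multi-component outcomes
#' (credit card misuse, financial health, forward-looking behaviors), the
#' composite self-regulation index, and the capital-formation index.
#'
#' @param components a list of numeric vectors of equal length, or a
#'   numeric matrix (columns = components). `NA` marks missing.
#' @param min_present minimum number of observed components for a
#'   participant to receive a score; defaults to half the components
#'   (rounded up). Use `length(components)` for complete-case behaviour.
#' @return numeric vector: the rank-normalized index, `NA` where fewer than
#'   `min_present` components are observed.
#' @export
equal_weight_index <- function(components,
                               min_present = ceiling(k / 2)) {
  if (is.list(components)) components <- do.call(cbind, components)
  if (!is.matrix(components)) components <- as.matrix(components)
  k <- ncol(components)
  force(min_present)
  if (k < 1L) stop("need at least one component")
  if (all(is.na(components)))
    stop("degenerate input: all components missing for all participants")
  z <- apply(components, 2L, rank_inverse_normal)
  n_obs <- rowSums(!is.na(z))
  avg <- rowMeans(z, na.rm = TRUE)
  avg[n_obs < min_present] <- NA_real_
  avg[is.nan(avg)] <- NA_real_
  rng <- range(avg, na.rm = TRUE)
  if (diff(rng) <= 1e-10 * (1 + max(abs(rng))))
    stop("degenerate index: components cancel to a constant")
  rank_inverse_normal(avg)
}

#' Score a CCQ-style item battery into a self-regulation index
#'
#' For one assessment age: reverse negatively keyed items, average the items
#' within each subscale, rank-normalize each subscale score, average the six
#' subscale scores with equal weight, and rank-normalize the result.
#' Participants missing more than half of a subscale's items get a missing
#' subscale score; participants with fewer than `min_subscales` observed
#' subscale scores get a missing index.
#'
#' @param ratings participant-by-item numeric matrix with item ids as column
#'   names.
#' @param defs list of subscale definitions (`name`, `items`, `signs`), as
#'   produced by [default_ccq_subscales()] or supplied as configuration.
#' @param min_subscales minimum observed subscales (default: half, i.e. 3).
#' @return rank-normalized index, one value per row of `ratings`.
#' @export
score_ccq <- function(ratings, defs,
                      min_subscales = ceiling(length(defs) / 2)) {
  stopifnot(is.matrix(ratings))
  missing_items <- setdiff(unlist(lapply(defs, `[[`, "items")),
                           colnames(ratings))
  if (length(missing_items))
    stop("subscale definitions reference unknown items: ",
         paste(utils::head(missing_items, 5), collapse = ", "))
  sub_scores <- vapply(defs, function(d) {
    keyed <- sweep(ratings[, d$items, drop = FALSE], 2L, d$signs, `*`)
    n_obs <- rowSums(!is.na(keyed))
    s <- rowMeans(keyed, na.rm = TRUE)
    s[n_obs < ceiling(length(d$items) / 2)] <- NA_real_
    s
  }, numeric(nrow(ratings)))
  equal_weight_index(sub_scores, min_present = min_subscales)
}

#' Composite self-regulation index (RNSRI)
#'
#' Equal-weighted mean of the rank-normalized preschool delay score (RND)
#' and the rank-normalized CCQ indices at the three assessment ages,
#' re-rank-normalized. Participants with fewer than `min_present` of the
#' four components are missing.
#'
#' @param rnd,rnccq_17,rnccq_27,rnccq_37 numeric score vectors aligned on
#'   the same participants.
#' @param min_present minimum observed components (default 2 of 4).
#' @return list with `rnsri` and the (re-normalized) component vectors
#'   `rnccq_17`, `rnccq_27`, `rnccq_37`.
#' @export
compute_rnsri <- function(rnd, rnccq_17, rnccq_27, rnccq_37,
                          min_present = 2L) {
  n <- length(rnd)
  stopifnot(length(rnccq_17) == n, length(rnccq_27) == n,
            length(rnccq_37) == n)
  comp <- cbind(rnd = rnd, rnccq_17 = rnccq_17, rnccq_27 = rnccq_27,
                rnccq_37 = rnccq_37)
  list(
    rnsri = equal_weight_index(comp, min_present = min_present),
    rnccq_17 = rnccq_17, rnccq_27 = rnccq_27, rnccq_37 = rnccq_37
  )
}

#' Build the analysis-ready participant-by-variable table
#'
#' Assembles, for the survey subsample of a cohort, every variable the
#' inference battery uses: the 11 rank-normalized outcomes (reverse-scaled
#' where flagged), the rank-normalized CCQ index at each assessment age,
#' RND, and RNSRI. All transformations are applied within the set of
#' participants observed for each variable.
#'
#' @param cohort a [generate_cohort()] result (or a list with the same
#'   `ccq`/`outcomes`/`participants` structure read from files).
#' @param rnd_scores data frame from [compute_rnd()] (full cohort; the
#'   survey rows are extracted by participant id).
#' @param subscale_defs optional list of per-age subscale definition lists;
#'   defaults to [default_ccq_subscales()] applied to the cohort's item
#'   spec.
#' @return data frame keyed by `participant_id` with `male`, `diagnostic`,
#'   outcome columns, `rnd`, `rnccq_17/27/37`, `rnsri`.
#' @export
build_analysis_table <- function(cohort, rnd_scores,
                                 subscale_defs = NULL) {
  os <- cohort$spec$outcome_spec
  out <- cohort$outcomes
  pid <- out$participant_id
  tbl <- data.frame(participant_id = pid, stringsAsFactors = FALSE)
  part <- cohort$participants
  tbl$male <- part$male[match(pid, part$participant_id)]
  tbl$diagnostic <- part$diagnostic[match(pid, part$participant_id)]

  for (k in seq_len(nrow(os))) {
    v <- out[[os$name[k]]]
    if (os$reverse[k]) v <- reverse_scale(v)
    tbl[[os$name[k]]] <- rank_inverse_normal(v)
  }

  ages <- cohort$spec$item_spec$ages
  if (is.null(subscale_defs))
    subscale_defs <- lapply(seq_along(ages), function(j)
      default_ccq_subscales(ages[j], cohort$spec$item_spec$n_items[j]))
  rnccq <- lapply(seq_along(ages), function(j)
    score_ccq(cohort$ccq[[j]], subscale_defs[[j]]))

  tbl$rnd <- rnd_scores$rnd[match(pid, rnd_scores$participant_id)]
  # re-normalize RND within the survey subsample: scores measure relative
  # standing within the sample entering the battery
  tbl$rnd <- rank_inverse_normal(tbl$rnd)
  sri <- compute_rnsri(tbl$rnd, rnccq[[1]], rnccq[[2]], rnccq[[3]])
  tbl$rnccq_17 <- sri$rnccq_17
  tbl$rnccq_27 <- sri$rnccq_27
  tbl$rnccq_37 <- sri$rnccq_37
  tbl$rnsri <- sri$rnsri
  tbl
}

#' Names of the outcome battery columns
#'
#' @return character vector of the 11 outcome column names, in battery
#'   order.
#' @export
outcome_names <- function() default_outcome_spec()$name
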