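# Survival validation of the sampled cohort: per-stratum one-sample
# log-rank tests against the stratum population's Nelson-Aalen hazard, and
# cohort-level Kaplan-Meier comparison and follow-up summaries.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator (via the survival package); ties between events
#' and censorings at the same time are handled events-first, the standard
#' convention. The curve starts at 1 and drops only at event times.
#'
#' @param times nonnegative follow-up times
#' @param events event indicators (1 death, 0 censored)
#' @return object of class `km_curve`: tibble with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(times) == length(events), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        survival = fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}

# Evaluate a KM curve as a right-continuous step function (1 before the
# first time point).
km_survival_at <- function(km, t) {
  stats::stepfun(km$time, c(1, km$survival), right = FALSE)(t)
}

#' Supremum distance between two Kaplan-Meier curves
#'
#' @param km1,km2 `km_curve` objects
#' @return max absolute difference of the step functions over all jump times
#' @export
km_sup_distance <- function(km1, km2) {
  grid <- sort(unique(c(0, km1$time, km2$time)))
  max(abs(km_survival_at(km1, grid) - km_survival_at(km2, grid)))
}

#' Nelson-Aalen cumulative hazard of a reference population
#'
#' Lambda(t) = sum over event times t_i <= t of d_i / n_i, with d_i events
#' and n_i at risk; flat beyond the last observed time, 0 before the first
#' event.
#'
#' @param times,events population follow-up times and event indicators
#' @return object of class `reference_hazard` with `time` and `cumhaz`
#' @export
reference_cumulative_hazard <- function(times, events) {
  if (length(times) == 0) stop("empty population", call. = FALSE)
  ord <- order(times)
  t_s <- times[ord]; e_s <- events[ord]
  te <- t_s[e_s == 1]
  if (length(te) == 0) {
    res <- list(time = numeric(0), cumhaz = numeric(0))
  } else {
    ut <- unique(te)
    d <- tabulate(match(te, ut))
    # at risk: everyone with follow-up >= t (events-first tie handling)
    n_risk <- length(t_s) - findInterval(ut, t_s, left.open = TRUE)
    res <- list(time = ut, cumhaz = cumsum(d / n_risk))
  }
  class(res) <- "reference_hazard"
  res
}

#' Evaluate a reference cumulative hazard at given times
#'
#' @param reference a `reference_hazard`
#' @param t evaluation times
#' @return Lambda(t), flat beyond the last event time
#' @export
cumhaz_at <- function(reference, t) {
  if (length(reference$time) == 0) return(rep(0, length(t)))
  idx <- findInterval(t, reference$time)
  c(0, reference$cumhaz)[idx + 1]
}

#' One-sample log-rank test against a reference population
#'
#' Compares a sample's survival experience with a reference population's
#' cumulative hazard: observed events O, expected events
#' E = sum_i Lambda(T_i) over the sample's follow-up times,
#' Z = (O - E) / sqrt(E), with a two-sided p-value from the standard
#' normal. When the sample is the reference population itself, O = E
#' exactly and p = 1.
#'
#' @param times,events sample follow-up times and event indicators
#' @param reference a [reference_cumulative_hazard()] (extended flat beyond
#'   its last event time)
#' @param alpha significance level for the pass verdict
#' @return list: `observed`, `expected`, `statistic`, `p_value`, `pass`,
#'   `undefined` (TRUE when E = 0 with O > 0, reported as a fail)
#' @export
one_sample_logrank <- function(times, events, reference, alpha = 0.05) {
  if (length(times) == 0) stop("empty sample", call. = FALSE)
  O <- sum(events)
  E <- sum(cumhaz_at(reference, times))
  if (E == 0) {
    if (O == 0)
      return(list(observed = 0, expected = 0, statistic = 0, p_value = 1,
                  pass = TRUE, undefined = FALSE))
    return(list(observed = O, expected = 0, statistic = Inf, p_value = 0,
                pass = FALSE, undefined = TRUE))
  }
  Z <- (O - E) / sqrt(E)
  p <- 2 * stats::pnorm(-abs(Z))
  list(observed = O, expected = E, statistic = Z, p_value = p,
       pass = p > alpha, undefined = FALSE)
}

#' Proportion of strata passing the log-rank check
#'
#' @param results data frame with a logical `pass` column (one row per
#'   stratum), or a list of log-rank results
#' @return fraction of strata whose test did not reject
#' @export
stratum_pass_proportion <- function(results) {
  pass <- if (is.data.frame(results)) results$pass
          else vapply(results, `[[`, logical(1), "pass")
  if (length(pass) == 0) stop("no log-rank results", call. = FALSE)
  mean(pass)
}

#' Follow-up time summary
#'
#' Order statistics of follow-up time regardless of event status (the
#' convention under which the minimum of 0 years is reported).
#'
#' @param times follow-up times
#' @return list with `median`, `min`, `max`
#' @export
follow_up_summary <- function(times) {
  if (length(times) == 0) stop("empty input", call. = FALSE)
  list(median = stats::median(times), min = min(times), max = max(times))
}

#' Validate a sampled cohort's survival against its population
#'
#' Per stratum: Nelson-Aalen reference hazard from the full stratum
#' population (the sample is a subset of it by design) and a one-sample
#' log-rank test on the sample. Per cancer type: pass proportions over all
#' strata and over strata with at least `min_events` observed events,
#' Kaplan-Meier curves for population and sample with their sup-distance,
#' and follow-up summaries.
#'
#' @param population eligible population table
#' @param result a `sampling_result`
#' @param strata the kept strata the result was drawn from
#' @param alpha significance level
#' @param min_events event-count floor for the restricted pass proportion
#' @return list with `per_stratum`, `pass_rates`, `km_comparison`,
#'   `follow_up`
#' @export
validate_cohort <- function(population, result, strata, alpha = 0.05,
                            min_events = 5L) {
  idx_by_id <- match(result$per_stratum$stratum_id, strata$stratum_id)
  rows <- vector("list", nrow(result$per_stratum))
  for (h in seq_len(nrow(result$per_stratum))) {
    st <- strata[idx_by_id[h], ]
    pop_rows <- population[match(st$member_ids[[1]], population$patient_id), ]
    smp_rows <- population[match(result$per_stratum$member_ids[[h]],
                                 population$patient_id), ]
    ref <- reference_cumulative_hazard(pop_rows$time_years, pop_rows$event)
    lr <- one_sample_logrank(smp_rows$time_years, smp_rows$event, ref, alpha)
    rows[[h]] <- tibble::tibble(
      stratum_id = st$stratum_id, cancer_type = st$cancer_type,
      n_sample = nrow(smp_rows), observed = lr$observed,
      expected = lr$expected, statistic = lr$statistic,
      p_value = lr$p_value, pass = lr$pass, undefined = lr$undefined)
  }
  per_stratum <- dplyr::bind_rows(rows)
  pass_rates <- per_stratum |>
    dplyr::group_by(.data$cancer_type) |>
    dplyr::summarise(
      n_strata = dplyr::n(),
      pass_rate_all = mean(.data$pass),
      n_strata_min_events = sum(.data$observed >= min_events),
      pass_rate_min_events = ifelse(sum(.data$observed >= min_events) > 0,
                                    mean(.data$pass[.data$observed >=
                                                      min_events]), NA_real_),
      .groups = "drop")

  cohort <- population[match(result$cohort_ids, population$patient_id), ]
  km_comparison <- lapply(
    stats::setNames(unique(per_stratum$cancer_type),
                    unique(per_stratum$cancer_type)),
    function(cc) {
      pop_cc <- population[population$cancer_type == cc &
                             population$patient_id %in%
                               unlist(strata$member_ids[strata$cancer_type ==
                                                          cc]), ]
      smp_cc <- cohort[cohort$cancer_type == cc, ]
      km_pop <- kaplan_meier(pop_cc$time_years, pop_cc$event)
      km_smp <- kaplan_meier(smp_cc$time_years, smp_cc$event)
      list(population = km_pop, sample = km_smp,
           sup_distance = km_sup_distance(km_pop, km_smp),
           follow_up_population = follow_up_summary(pop_cc$time_years),
           follow_up_sample = follow_up_summary(smp_cc$time_years))
    })
  list(per_stratum = per_stratum, pass_rates = pass_rates,
       km_comparison = km_comparison)
}

#' Monte-Carlo size/power of the one-sample log-rank test
#'
#' Each replicate builds a fresh reference population (exponential deaths,
#' staggered administrative censoring) and an independent sample from the
#' same law with its hazard scaled by `hazard_ratio`; under `hazard_ratio
#' = 1` the rejection rate estimates the test's size. The sample is drawn
#' independently of the reference population (equivalently, SRSWOR at a
#' negligible fraction of a large population): when the sample is instead a
#' sizable subset of its own reference, the classic statistic is
#' conservative because O and the estimated hazard are positively
#' correlated.
#'
#' @param n_reps replicate strata
#' @param n_pop reference population size per replicate
#' @param n_sample sample size per replicate
#' @param event_rate exponential death rate (per year)
#' @param hazard_ratio multiplier on the sample's death rate
#' @param censor_range administrative censoring window (uniform, years)
#' @param alpha significance level
#' @return list with `rejection_rate`, `n_reps`, `mean_events`
#' @export
logrank_size_simulation <- function(n_reps = 2000, n_pop = 10000,
                                    n_sample = 100, event_rate = 0.3,
                                    hazard_ratio = 1,
                                    censor_range = c(1, 9), alpha = 0.05) {
  reject <- logical(n_reps)
  events <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    death_p <- stats::rexp(n_pop, event_rate)
    cens_p <- stats::runif(n_pop, censor_range[1], censor_range[2])
    ref <- reference_cumulative_hazard(pmin(death_p, cens_p),
                                       as.integer(death_p <= cens_p))
    death_s <- stats::rexp(n_sample, event_rate * hazard_ratio)
    cens_s <- stats::runif(n_sample, censor_range[1], censor_range[2])
    lr <- one_sample_logrank(pmin(death_s, cens_s),
                             as.integer(death_s <= cens_s), ref, alpha)
    reject[r] <- !lr$pass
    events[r] <- lr$observed
  }
  list(rejection_rate = mean(reject), n_reps = n_reps,
       mean_events = mean(events))
}
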