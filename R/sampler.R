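# Stratified random sampling with proportional allocation and a
# representativeness guarantee: within each stratum, simple random samples
# without replacement (SRSWOR) are drawn until the stratum's population
# mean annual cost lies inside the sample's finite-population-correction
# (FPC) 95% confidence interval; failing candidates trigger resampling (up
# to a cap) with closest-mean selection, then incremental sample-size
# augmentation. Termination is guaranteed because a census is always
# representative.

#' Sampler configuration
#'
#' @param sampling_rate per-stratum sampling fraction in (0, 1]; default
#'   0.20, the rate the released cohorts were drawn at
#' @param z_value normal quantile of the confidence interval (1.96 = 95%)
#' @param max_candidates candidate draws per sample size before augmenting
#' @param augmentation_step sample-size increment when no candidate is
#'   representative
#' @param relative_margin relative margin of error for the theoretical
#'   sample-size report (default 1%)
#' @param always_best_of_k if TRUE, always draw `max_candidates` candidates
#'   and keep the representative one closest to the population mean, even
#'   when the first draw is already representative; the default keeps the
#'   first draw when it passes (resampling only on failure)
#' @param seed master seed; per-stratum substreams are derived from it
#' @return object of class `sampler_config`
#' @export
sampler_config <- function(sampling_rate = 0.20, z_value = 1.96,
                           max_candidates = 50L, augmentation_step = 1L,
                           relative_margin = 0.01,
                           always_best_of_k = FALSE, seed = 1L) {
  stopifnot(sampling_rate > 0, sampling_rate <= 1, max_candidates >= 1,
            augmentation_step >= 1)
  structure(list(sampling_rate = sampling_rate, z_value = z_value,
                 max_candidates = as.integer(max_candidates),
                 augmentation_step = as.integer(augmentation_step),
                 relative_margin = relative_margin,
                 always_best_of_k = always_best_of_k,
                 seed = as.integer(seed)),
            class = "sampler_config")
}

#' FPC confidence interval for a stratum sample mean
#'
#' The 95% interval for sampling without replacement from a finite stratum:
#' ybar_h +/- z * sqrt((N_h - n_h) / (N_h - 1)) * sigma_h / sqrt(n_h), with
#' sigma_h the known population SD. Degenerates to the point {ybar_h} at a
#' census or when sigma_h = 0.
#'
#' @param sample_mean sample mean ybar_h
#' @param sigma_h population SD of the stratum
#' @param N_h,n_h population and sample sizes, 1 <= n_h <= N_h
#' @param z_value normal quantile
#' @return list with `ci_low`, `ci_high`, `half_width` (vectorised)
#' @export
fpc_confidence_interval <- function(sample_mean, sigma_h, N_h, n_h,
                                    z_value = 1.96) {
  if (any(n_h < 1)) stop("n_h must be at least 1", call. = FALSE)
  if (any(n_h > N_h)) stop("n_h cannot exceed N_h", call. = FALSE)
  if (any(sigma_h < 0)) stop("sigma_h must be nonnegative", call. = FALSE)
  fpc <- ifelse(n_h == N_h, 0, sqrt((N_h - n_h) / (N_h - 1)))
  half <- z_value * fpc * sigma_h / sqrt(n_h)
  list(ci_low = sample_mean - half, ci_high = sample_mean + half,
       half_width = half)
}

#' Smallest sample size achieving a relative margin of error
#'
#' Smallest n such that the FPC interval half-width at (sigma_h, N_h) does
#' not exceed `relative_margin * pop_mean`: the infinite-population size
#' n0 = (z * sigma_h / d)^2 is deflated by the finite-population factor,
#' n = N * n0 / (n0 + N - 1), then rounded up and capped at N_h. Used to
#' report how far above the theoretical requirement a 20% allocation sits.
#'
#' @param pop_mean stratum population mean (must be positive)
#' @param sigma_h population SD
#' @param N_h stratum population size
#' @param relative_margin relative margin of error (0.01 = 1%)
#' @param z_value normal quantile
#' @return integer sample size
#' @export
margin_of_error_size <- function(pop_mean, sigma_h, N_h,
                                 relative_margin = 0.01, z_value = 1.96) {
  if (any(pop_mean <= 0))
    stop("pop_mean must be positive for a relative margin", call. = FALSE)
  if (any(relative_margin <= 0))
    stop("relative_margin must be positive", call. = FALSE)
  d <- relative_margin * pop_mean
  n0 <- (z_value * sigma_h / d)^2
  n <- ceiling(N_h * n0 / (n0 + N_h - 1) - 1e-9)
  as.integer(pmin(N_h, pmax(1, n)))
}

#' Proportional allocation of the stratum sample size
#'
#' n_h = min(N_h, ceiling(rate * N_h)); the ceiling guarantees a nonempty
#' sample in every stratum.
#'
#' @param N_h stratum population size
#' @param sampling_rate sampling fraction
#' @return integer sample size(s)
#' @export
allocate_sample_size <- function(N_h, sampling_rate = 0.20) {
  stopifnot(all(N_h >= 1))
  as.integer(pmin(N_h, pmax(1, ceiling(sampling_rate * N_h - 1e-9))))
}

#' Draw one SRSWOR candidate sample from a stratum
#'
#' Uniform over size-n_h subsets of the stratum members. The candidate
#' carries its mean, FPC interval and representativeness verdict (the
#' stratum population mean inside the closed interval).
#'
#' @param stratum one row of [build_strata()] output (data frame or list)
#' @param n_h sample size, 1 <= n_h <= N_h
#' @param z_value normal quantile for the interval
#' @param candidate_index index recorded on the candidate
#' @return list: member_ids, n_h, sample_mean, ci_low, ci_high,
#'   representative, candidate_index
#' @export
draw_candidate <- function(stratum, n_h, z_value = 1.96,
                           candidate_index = 1L) {
  ids <- stratum$member_ids[[1]]
  costs <- stratum$member_costs[[1]]
  N_h <- stratum$N_h[[1]]
  if (n_h > N_h) stop("n_h cannot exceed N_h", call. = FALSE)
  pick <- if (n_h == N_h) seq_len(N_h) else sample.int(N_h, n_h)
  m <- mean(costs[pick])
  ci <- fpc_confidence_interval(m, stratum$sigma_h[[1]], N_h, n_h, z_value)
  list(member_ids = ids[pick], n_h = as.integer(n_h), sample_mean = m,
       ci_low = ci$ci_low, ci_high = ci$ci_high,
       representative = stratum$pop_mean[[1]] >= ci$ci_low &&
         stratum$pop_mean[[1]] <= ci$ci_high,
       candidate_index = as.integer(candidate_index))
}

#' Select the final sample for one stratum
#'
#' Algorithm: (1) allocate n_h proportionally; (2) draw a first candidate
#' and accept it if representative (unless `always_best_of_k`); (3)
#' otherwise draw up to `max_candidates` candidates at this n_h and accept,
#' among the representative ones, the candidate whose mean is closest to
#' the population mean (ties to the earliest draw); (4) if none is
#' representative, augment n_h by `augmentation_step` (capped at N_h) and
#' repeat. A census is always representative, so the loop terminates.
#'
#' @param stratum one stratum row
#' @param config a [sampler_config()]
#' @return list: chosen candidate fields plus `n_initial`, `attempts`
#'   (total candidates drawn), `augmented`, and `candidate_means` log
#' @export
select_stratum_sample <- function(stratum, config = sampler_config()) {
  N_h <- stratum$N_h[[1]]
  pop_mean <- stratum$pop_mean[[1]]
  n_init <- allocate_sample_size(N_h, config$sampling_rate)
  n_h <- n_init
  attempts <- 0L
  means_log <- numeric(0)
  repeat {
    cands <- list()
    for (i in seq_len(config$max_candidates)) {
      cand <- draw_candidate(stratum, n_h, config$z_value, i)
      attempts <- attempts + 1L
      means_log <- c(means_log, cand$sample_mean)
      cands[[i]] <- cand
      if (i == 1L && cand$representative && !config$always_best_of_k)
        break
      if (n_h == N_h) break  # census: one draw settles it
    }
    reps <- Filter(function(cc) cc$representative, cands)
    if (length(reps) > 0) {
      dist <- vapply(reps, function(cc) abs(cc$sample_mean - pop_mean),
                     numeric(1))
      chosen <- reps[[which.min(dist)]]   # which.min takes the earliest tie
      return(c(chosen,
               list(n_initial = n_init, attempts = attempts,
                    augmented = n_h > n_init,
                    candidate_means = list(means_log))))
    }
    n_h <- min(N_h, n_h + config$augmentation_step)
  }
}

#' Sample a representative cohort across all strata
#'
#' Runs [select_stratum_sample()] for every stratum, each on an independent
#' RNG substream derived from the master seed and the stratum key, and
#' assembles the cohort. Reports the realised sampling fraction per cancer
#' type (slightly above the nominal rate because of ceiling allocation and
#' augmentation).
#'
#' @param strata kept strata from [suppress_small_strata()]
#' @param config a [sampler_config()]
#' @return object of class `sampling_result`: `per_stratum` tibble,
#'   `cohort_ids`, `fractions` per cancer type, and the config
#' @export
sample_cohort <- function(strata, config = sampler_config()) {
  if (nrow(strata) == 0) {
    res <- list(per_stratum = tibble::tibble(), cohort_ids = integer(),
                fractions = tibble::tibble(), config = config)
    class(res) <- "sampling_result"
    return(res)
  }
  rows <- vector("list", nrow(strata))
  for (h in seq_len(nrow(strata))) {
    st <- strata[h, ]
    set.seed(stratum_seed(config$seed, st$stratum_id))
    sel <- select_stratum_sample(st, config)
    rows[[h]] <- tibble::tibble(
      stratum_id = st$stratum_id, cancer_type = st$cancer_type,
      N_h = st$N_h, n_initial = sel$n_initial, final_n_h = sel$n_h,
      attempts = sel$attempts, augmented = sel$augmented,
      candidate_index = sel$candidate_index,
      sample_mean = sel$sample_mean, pop_mean = st$pop_mean,
      sigma_h = st$sigma_h, ci_low = sel$ci_low, ci_high = sel$ci_high,
      representative = sel$representative,
      member_ids = list(sel$member_ids),
      candidate_means = sel$candidate_means)
  }
  per_stratum <- dplyr::bind_rows(rows)
  stopifnot(all(per_stratum$representative))  # guarantee by construction
  fractions <- per_stratum |>
    dplyr::group_by(.data$cancer_type) |>
    dplyr::summarise(population_n = sum(.data$N_h),
                     sample_n = sum(.data$final_n_h), .groups = "drop") |>
    dplyr::mutate(fraction = .data$sample_n / .data$population_n)
  res <- list(per_stratum = per_stratum,
              cohort_ids = unlist(per_stratum$member_ids),
              fractions = fractions, config = config)
  class(res) <- "sampling_result"
  res
}
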