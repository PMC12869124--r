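# Seeded synthetic cancer-registry generator. The real cohorts are built
# from access-restricted linked registry/claims data; this module emulates
# the joint structure the sampler and validators assume: published marginal
# distributions of age, sex, region, SEER stage and diagnosis year, a
# right-skewed annual-cost model, and survival with administrative
# censoring at a fixed calendar cutoff.

#' Configuration for the synthetic registry population
#'
#' Defaults are calibrated to the published cohort marginals: categorical
#' weights for age group, sex, SEER stage and diagnosis year are the
#' published population proportions per cancer type, and the lognormal cost
#' model matches the published per cancer-by-age cost means and SDs (means
#' approximately 7,900-14,000 USD with SDs of the same order, hence the
#' lognormal choice). Region weights over the 17 first-level divisions are
#' not published at that resolution and approximate national population
#' shares.
#'
#' @param cancer_types character vector of cancer labels
#' @param n_per_cancer rows to generate per cancer type
#' @param year_range inclusive diagnosis-year range
#' @param age_distribution named list (per cancer) of weights over the six
#'   age groups
#' @param sex_ratio named numeric, male fraction per cancer (0 for breast)
#' @param region_weights named weights over the 17 regions
#' @param stage_weights named list (per cancer) of weights over SEER stages;
#'   liver assigns zero weight to "in situ"
#' @param year_weights named list (per cancer) of weights over diagnosis years
#' @param cost_model named list (per cancer) of lists with `meanlog`,
#'   `sdlog` vectors over age groups (lognormal annual cost, USD)
#' @param hazard_model list with `base_rate` (per cancer, events/year),
#'   `stage_multiplier`, `age_multiplier`, and piecewise time effects
#'   `piece_breaks` / `piece_rel_rates`
#' @param censor_cutoff_year administrative censoring at Dec 31 of this year
#' @param secondary_rate fraction flagged as secondary cancers
#' @param missing_rate fraction with one required field set missing
#' @param seed integer seed; generation is a pure function of the config
#' @return object of class `population_config`
#' @export
population_config <- function(cancer_types = c("stomach", "breast",
                                               "colorectal", "liver"),
                              n_per_cancer = 10000,
                              year_range = c(2012, 2019),
                              age_distribution = NULL,
                              sex_ratio = NULL,
                              region_weights = NULL,
                              stage_weights = NULL,
                              year_weights = NULL,
                              cost_model = NULL,
                              hazard_model = NULL,
                              censor_cutoff_year = 2021,
                              secondary_rate = 0.02,
                              missing_rate = 0.02,
                              seed = 1L) {
  pub <- published_cohort_counts()
  per_cancer_weights <- function(var, levels) {
    out <- lapply(cancer_types, function(cc) {
      sub <- pub[pub$cancer_type == cc & pub$variable == var, ]
      if (nrow(sub) == 0) { # cancer not in the published tables: uniform
        w <- stats::setNames(rep(1 / length(levels), length(levels)), levels)
      } else {
        w <- stats::setNames(rep(0, length(levels)), levels)
        w[sub$level] <- sub$population_n
        w <- w / sum(w)
      }
      w
    })
    stats::setNames(out, cancer_types)
  }

  if (is.null(age_distribution))
    age_distribution <- per_cancer_weights("age_group", age_group6_levels())
  if (is.null(stage_weights))
    stage_weights <- per_cancer_weights("seer_stage", seer_stage_levels())
  if (is.null(year_weights))
    year_weights <- per_cancer_weights("year",
                                       as.character(year_range[1]:year_range[2]))
  if (is.null(sex_ratio)) {
    sex_ratio <- vapply(cancer_types, function(cc) {
      sub <- pub[pub$cancer_type == cc & pub$variable == "sex", ]
      if (nrow(sub) == 0) return(0.5)
      male <- sub$population_n[sub$level == "male"]
      if (length(male) == 0) 0 else male / sum(sub$population_n)
    }, numeric(1))
  }
  if (is.null(region_weights)) {
    region_weights <- stats::setNames(
      c(0.184, 0.065, 0.047, 0.057, 0.028, 0.028, 0.022, 0.007, 0.260,
        0.030, 0.031, 0.041, 0.035, 0.036, 0.051, 0.065, 0.013),
      region17_levels())
  }
  if (is.null(cost_model)) {
    costs <- published_cost_summary()
    cost_model <- lapply(stats::setNames(cancer_types, cancer_types),
                         function(cc) {
      sub <- costs[costs$cancer_type == cc, ]
      if (nrow(sub) == 0) {
        m <- rep(10000, 6); s <- rep(10000, 6)
      } else {
        m <- sub$pop_mean[match(age_group6_levels(), sub$age_group)]
        s <- sub$pop_sd[match(age_group6_levels(), sub$age_group)]
      }
      sdlog <- sqrt(log(1 + (s / m)^2))
      list(meanlog = stats::setNames(log(m) - sdlog^2 / 2,
                                     age_group6_levels()),
           sdlog = stats::setNames(sdlog, age_group6_levels()))
    })
  }
  if (is.null(hazard_model)) {
    hazard_model <- list(
      base_rate = stats::setNames(
        c(0.10, 0.03, 0.08, 0.25)[match(cancer_types,
                                        c("stomach", "breast",
                                          "colorectal", "liver"))],
        cancer_types),
      stage_multiplier = c("in situ" = 0.1, localized = 0.4, regional = 1.0,
                           distant = 4.0, unknown = 1.2),
      age_multiplier = stats::setNames(c(0.6, 0.7, 0.85, 1.0, 1.4, 2.2),
                                       age_group6_levels()),
      piece_breaks = c(0, 1, 3),
      piece_rel_rates = c(1.6, 1.0, 0.6))
    hazard_model$base_rate[is.na(hazard_model$base_rate)] <- 0.1
  }

  cfg <- list(cancer_types = cancer_types, n_per_cancer = n_per_cancer,
              year_range = year_range, age_distribution = age_distribution,
              sex_ratio = sex_ratio, region_weights = region_weights,
              stage_weights = stage_weights, year_weights = year_weights,
              cost_model = cost_model, hazard_model = hazard_model,
              censor_cutoff_year = censor_cutoff_year,
              secondary_rate = secondary_rate, missing_rate = missing_rate,
              seed = as.integer(seed))
  class(cfg) <- "population_config"
  validate_population_config(cfg)
  cfg
}

validate_population_config <- function(cfg) {
  check_weights <- function(w, what) {
    if (any(w < 0) || abs(sum(w) - 1) > 1e-6)
      stop("configuration error: ", what,
           " weights must be nonnegative and sum to 1", call. = FALSE)
  }
  for (cc in cfg$cancer_types) {
    check_weights(cfg$age_distribution[[cc]], paste0("age (", cc, ")"))
    check_weights(cfg$stage_weights[[cc]], paste0("stage (", cc, ")"))
    check_weights(cfg$year_weights[[cc]], paste0("year (", cc, ")"))
    sr <- cfg$sex_ratio[[cc]]
    if (is.na(sr) || sr < 0 || sr > 1)
      stop("configuration error: male fraction must lie in [0, 1]",
           call. = FALSE)
  }
  check_weights(cfg$region_weights, "region")
  if (any(unlist(cfg$hazard_model[c("base_rate", "stage_multiplier",
                                    "age_multiplier",
                                    "piece_rel_rates")]) <= 0))
    stop("configuration error: hazard multipliers must be positive",
         call. = FALSE)
  if (cfg$n_per_cancer < 0)
    stop("configuration error: n_per_cancer must be nonnegative",
         call. = FALSE)
  invisible(cfg)
}

# Latent death time for a piecewise-exponential hazard: rate(t) =
# rate0 * piece_rel_rates[j] on [breaks[j], breaks[j+1]), last piece open.
# Inverse-transform on the cumulative hazard; vectorised over rate0.
piecewise_exp_time <- function(rate0, breaks, rel_rates, u = NULL) {
  if (is.null(u)) u <- stats::runif(length(rate0))
  target <- -log(u) / rate0            # required baseline-scale cum hazard
  widths <- diff(breaks)
  piece_ch <- c(0, cumsum(widths * rel_rates[seq_along(widths)]))
  j <- findInterval(target, piece_ch)  # piece index holding the target
  j <- pmin(j, length(rel_rates))
  breaks[j] + (target - piece_ch[j]) / rel_rates[j]
}

#' Draw survival time with administrative censoring
#'
#' Latent death times follow a piecewise-exponential hazard with stage, age
#' and per-cancer multipliers. Follow-up is censored administratively at
#' December 31 of the cutoff year; within-year diagnosis timing is uniform
#' unless supplied. A record is censored exactly when its latent death time
#' exceeds the administrative window.
#'
#' @param stage,age_group,diagnosis_year vectors (recycled to a common
#'   length) of SEER stage, six-level age group, and diagnosis year
#' @param hazard_model as in [population_config()]
#' @param censor_cutoff_year censoring calendar year
#' @param cancer_type optional per-record cancer label selecting
#'   `base_rate`; a single unnamed base rate is used otherwise
#' @param diag_frac within-year diagnosis timing in [0, 1); uniform if NULL
#' @return tibble with `time_years` and `event` (1 death, 0 censored)
#' @export
draw_survival_time <- function(stage, age_group, diagnosis_year,
                               hazard_model, censor_cutoff_year = 2021,
                               cancer_type = NULL, diag_frac = NULL) {
  n <- max(length(stage), length(age_group), length(diagnosis_year))
  stage <- rep_len(stage, n); age_group <- rep_len(age_group, n)
  diagnosis_year <- rep_len(diagnosis_year, n)
  base <- if (is.null(cancer_type)) {
    rep_len(unname(hazard_model$base_rate)[1], n)
  } else {
    unname(hazard_model$base_rate[rep_len(cancer_type, n)])
  }
  rate0 <- base * hazard_model$stage_multiplier[stage] *
    hazard_model$age_multiplier[age_group]
  if (any(is.na(rate0) | rate0 <= 0))
    stop("configuration error: hazard multipliers must be positive and ",
         "defined for every stage/age level", call. = FALSE)
  if (is.null(diag_frac)) diag_frac <- stats::runif(n)
  latent <- piecewise_exp_time(rate0, hazard_model$piece_breaks,
                               hazard_model$piece_rel_rates)
  window <- censor_cutoff_year + 1 - (diagnosis_year + diag_frac)
  tibble::tibble(time_years = pmin(latent, window),
                 event = as.integer(latent <= window))
}

#' Generate a synthetic registry population
#'
#' Draws `n_per_cancer` patient records per cancer type with independent
#' categorical marginals per the config, lognormal annual costs per
#' cancer-by-age cell, and survival with administrative censoring. A small
#' fraction of records is flagged as secondary cancers or given one missing
#' required field so the eligibility filter has work to do. Identical
#' config (including seed) yields an identical table.
#'
#' @param config a [population_config()]
#' @return tibble of patient records (one row per patient)
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  validate_population_config(config)
  schema <- tibble::tibble(patient_id = integer(), cancer_type = character(),
                           diagnosis_year = integer(), sex = character(),
                           age_at_diagnosis = integer(),
                           region17 = character(), seer_stage = character(),
                           secondary_cancer = logical(),
                           annual_cost_usd = double(),
                           time_years = double(), event = integer())
  if (config$n_per_cancer == 0) return(schema)

  set.seed(config$seed)
  ages <- age_group6_levels()
  age_lo <- c(18, 40, 50, 60, 70, 80); age_hi <- c(39, 49, 59, 69, 79, 94)
  out <- lapply(config$cancer_types, function(cc) {
    n <- config$n_per_cancer
    year_lv <- as.integer(names(config$year_weights[[cc]]))
    year <- sample(year_lv, n, TRUE, prob = config$year_weights[[cc]])
    sex <- ifelse(stats::runif(n) < config$sex_ratio[[cc]], "male", "female")
    grp_i <- sample(seq_along(ages), n, TRUE,
                    prob = config$age_distribution[[cc]])
    age <- age_lo[grp_i] +
      floor(stats::runif(n) * (age_hi[grp_i] - age_lo[grp_i] + 1L))
    region <- sample(names(config$region_weights), n, TRUE,
                     prob = config$region_weights)
    stage <- sample(names(config$stage_weights[[cc]]), n, TRUE,
                    prob = config$stage_weights[[cc]])
    cm <- config$cost_model[[cc]]
    cost <- stats::rlnorm(n, cm$meanlog[ages[grp_i]], cm$sdlog[ages[grp_i]])
    surv <- draw_survival_time(stage, ages[grp_i], year, config$hazard_model,
                               config$censor_cutoff_year, cancer_type = cc)
    tibble::tibble(cancer_type = cc, diagnosis_year = year, sex = sex,
                   age_at_diagnosis = as.integer(age), region17 = region,
                   seer_stage = stage,
                   secondary_cancer = stats::runif(n) < config$secondary_rate,
                   annual_cost_usd = cost,
                   time_years = surv$time_years, event = surv$event)
  })
  pop <- dplyr::bind_rows(out)
  pop$patient_id <- seq_len(nrow(pop))

  # inject missingness into one stratification field per affected record
  miss <- which(stats::runif(nrow(pop)) < config$missing_rate)
  if (length(miss) > 0) {
    field <- sample(c("age_at_diagnosis", "region17", "seer_stage"),
                    length(miss), TRUE)
    for (f in unique(field)) pop[miss[field == f], f] <- NA
  }
  dplyr::relocate(pop, "patient_id")
}
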