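# Descriptive reporting of the constructed cohorts: population/sample
# counts with percentages by stratification variable, cost summaries by
# cancer type and age group, and the in-text style fractions and rate
# ratios. All display percentages use round-half-up at one decimal.

#' Sampling fraction as a printed percentage
#'
#' @param sample_n,population_n cohort and population counts
#' @return 100 * sample_n / population_n, round-half-up to one decimal
#' @export
sampling_fraction <- function(sample_n, population_n) {
  if (any(population_n == 0)) stop("population_n must be positive",
                                   call. = FALSE)
  stopifnot(all(sample_n >= 0), all(sample_n <= population_n))
  round_half_up(100 * sample_n / population_n, 1)
}

#' Proportion of patients in selected age groups
#'
#' @param counts named counts by the six age groups
#' @param groups subset of age-group labels to aggregate
#' @return percentage (one decimal, round-half-up)
#' @export
age_group_proportion <- function(counts, groups) {
  stopifnot(all(groups %in% names(counts)))
  total <- sum(counts)
  if (total == 0) stop("zero total count", call. = FALSE)
  round_half_up(100 * sum(counts[groups]) / total, 1)
}

#' Male-to-female rate ratio
#'
#' Computed as the count ratio (one-decimal round-half-up); person-time
#' denominators are not carried by the cohort tables.
#'
#' @param male_n,female_n counts by sex
#' @return ratio rounded to one decimal
#' @export
sex_rate_ratio <- function(male_n, female_n) {
  if (any(female_n == 0)) stop("female_n must be positive", call. = FALSE)
  round_half_up(male_n / female_n, 1)
}

#' Cost summary by cancer type and age group
#'
#' Per-cell n, mean and SD of annual medical cost. The SD here uses the
#' sample (n - 1) convention for reporting; the sampler's sigma_h keeps the
#' population convention.
#'
#' @param records patient table
#' @return tibble with one row per cancer-by-age cell
#' @export
cost_summary_table <- function(records) {
  stopifnot(nrow(records) > 0)
  records |>
    dplyr::mutate(age_group = recode_age_group(.data$age_at_diagnosis)) |>
    dplyr::group_by(.data$cancer_type, .data$age_group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_cost = mean(.data$annual_cost_usd),
                     sd_cost = stats::sd(.data$annual_cost_usd),
                     .groups = "drop")
}

#' Population/sample summary counts with percentages
#'
#' Long-format descriptive table: per cancer type, counts of population and
#' sample by age group, sex, 3-level region, SEER stage and incidence year,
#' with the sample percentage of the population per cell.
#'
#' @param population eligible population table
#' @param cohort sampled cohort table (subset of population rows)
#' @param region3_mapping named 17-to-3 region mapping
#' @return tibble: cancer_type, variable, level, population_n, sample_n, pct
#' @export
summary_count_table <- function(population, cohort,
                                region3_mapping = example_region3_mapping()) {
  prep <- function(df) {
    dplyr::mutate(df,
                  age_group = recode_age_group(.data$age_at_diagnosis),
                  region3 = recode_region(.data$region17, region3_mapping),
                  year = as.character(.data$diagnosis_year))
  }
  count_var <- function(df, var) {
    df |>
      dplyr::count(.data$cancer_type, level = .data[[var]]) |>
      dplyr::mutate(variable = var, level = as.character(.data$level))
  }
  vars <- c("age_group", "sex", "region3", "seer_stage", "year")
  pop_counts <- dplyr::bind_rows(lapply(vars, count_var, df = prep(population)))
  smp_counts <- dplyr::bind_rows(lapply(vars, count_var, df = prep(cohort)))
  pop_counts |>
    dplyr::rename(population_n = "n") |>
    dplyr::left_join(dplyr::rename(smp_counts, sample_n = "n"),
                     by = c("cancer_type", "variable", "level")) |>
    dplyr::mutate(sample_n = dplyr::coalesce(.data$sample_n, 0L),
                  pct = sampling_fraction(.data$sample_n,
                                          .data$population_n)) |>
    dplyr::select("cancer_type", "variable", "level", "population_n",
                  "sample_n", "pct")
}

#' Run the full cohort-construction pipeline
#'
#' Generate (or accept) a registry population, apply eligibility
#' exclusions, stratify, suppress small strata, draw the representative
#' sample, validate survival, and build the descriptive tables. When
#' `out_dir` is given, writes cohort.csv, attempts.csv, validation.csv,
#' exclusion_tally.csv, summary_counts.csv and cost_summary.csv.
#'
#' @param config a [population_config()]; ignored when `population` given
#' @param sampler a [sampler_config()]
#' @param rules an [eligibility_rules()]
#' @param region3_mapping named 17-to-3 region mapping for reporting
#' @param population optional pre-built registry table
#' @param out_dir optional output directory for CSV artifacts
#' @return list with all intermediate and final stages
#' @export
run_pipeline <- function(config = population_config(),
                         sampler = sampler_config(),
                         rules = eligibility_rules(),
                         region3_mapping = example_region3_mapping(),
                         population = NULL, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  registry <- stage("generate",
                    if (is.null(population)) generate_population(config)
                    else population)
  excl <- stage("prep", apply_exclusions(registry, rules))
  strata <- stage("prep", build_strata(excl$eligible))
  supp <- stage("prep", suppress_small_strata(strata, rules$min_stratum_size))
  result <- stage("sample", sample_cohort(supp$kept, sampler))
  cohort <- excl$eligible[match(result$cohort_ids,
                                excl$eligible$patient_id), , drop = FALSE]
  validation <- stage("validate",
                      validate_cohort(excl$eligible, result, supp$kept))
  counts <- stage("report",
                  summary_count_table(
                    excl$eligible[excl$eligible$patient_id %in%
                                    unlist(supp$kept$member_ids), ],
                    cohort, region3_mapping))
  costs <- stage("report", cost_summary_table(cohort))

  out <- list(registry = registry, exclusions = excl, strata = strata,
              suppression = supp, sampling = result, cohort = cohort,
              validation = validation, summary_counts = counts,
              cost_summary = costs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                          row.names = FALSE)
    w(cohort, "cohort.csv")
    w(dplyr::select(result$per_stratum, -"member_ids", -"candidate_means"),
      "attempts.csv")
    w(validation$per_stratum, "validation.csv")
    w(excl$tally, "exclusion_tally.csv")
    w(counts, "summary_counts.csv")
    w(costs, "cost_summary.csv")
  }
  invisible(out)
}
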