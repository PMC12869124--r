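# Eligibility exclusions, recodings, privacy suppression and
# stratification of the registry population.

#' Eligibility rules for the target population
#'
#' @param exclude_secondary drop records flagged as secondary cancers
#' @param required_fields fields that must be non-missing
#' @param breast_female_only restrict the breast-cancer population to females
#' @param min_stratum_size strata smaller than this are suppressed for
#'   privacy (small-cell suppression; default 5)
#' @param allowed_cancer_types recognised cancer labels; anything else in
#'   the input is an input error
#' @return object of class `eligibility_rules`
#' @export
eligibility_rules <- function(exclude_secondary = TRUE,
                              required_fields = c("age_at_diagnosis", "sex",
                                                  "region17",
                                                  "diagnosis_year",
                                                  "cancer_type",
                                                  "seer_stage"),
                              breast_female_only = TRUE,
                              min_stratum_size = 5L,
                              allowed_cancer_types = c("stomach", "breast",
                                                       "colorectal",
                                                       "liver")) {
  stopifnot(min_stratum_size >= 1)
  structure(list(exclude_secondary = exclude_secondary,
                 required_fields = required_fields,
                 breast_female_only = breast_female_only,
                 min_stratum_size = as.integer(min_stratum_size),
                 allowed_cancer_types = allowed_cancer_types),
            class = "eligibility_rules")
}

#' Apply eligibility exclusions
#'
#' Removes secondary cancers, records with a missing required field, and
#' (when enabled) male breast-cancer records. Each excluded record is
#' tallied under the first matching reason, in the order secondary ->
#' missing -> breast_male; eligibility itself does not depend on the order.
#'
#' @param registry patient table with the full record schema
#' @param rules an [eligibility_rules()]
#' @return list with `eligible` (retained rows) and `tally` (tibble of
#'   per-reason exclusion counts, zeros included)
#' @export
apply_exclusions <- function(registry, rules = eligibility_rules()) {
  known <- is.na(registry$cancer_type) |
    registry$cancer_type %in% rules$allowed_cancer_types
  if (!all(known))
    stop("input error: unknown cancer_type label(s): ",
         paste(unique(registry$cancer_type[!known]), collapse = ", "),
         call. = FALSE)

  secondary <- if (rules$exclude_secondary) {
    !is.na(registry$secondary_cancer) & registry$secondary_cancer
  } else rep(FALSE, nrow(registry))
  missing_any <- Reduce(`|`, lapply(rules$required_fields,
                                    function(f) is.na(registry[[f]])))
  if (is.null(missing_any)) missing_any <- rep(FALSE, nrow(registry))
  breast_male <- if (rules$breast_female_only) {
    !is.na(registry$cancer_type) & registry$cancer_type == "breast" &
      !is.na(registry$sex) & registry$sex == "male"
  } else rep(FALSE, nrow(registry))

  excluded_as <- rep(NA_character_, nrow(registry))
  excluded_as[breast_male] <- "breast_male"
  excluded_as[missing_any] <- "missing_field"
  excluded_as[secondary] <- "secondary_cancer"  # first-matching reason wins
  reasons <- c("secondary_cancer", "missing_field", "breast_male")
  counts <- vapply(reasons,
                   function(r) sum(excluded_as == r, na.rm = TRUE),
                   integer(1))
  tally <- tibble::tibble(reason = reasons, n = unname(counts))
  list(eligible = registry[is.na(excluded_as), , drop = FALSE],
       tally = tally)
}

#' Recode age at diagnosis into the six stratification groups
#'
#' Groups are 0-39, then 10-year intervals to 79, then >=80; small counts
#' below 40 and above 79 motivate the collapsed end groups.
#'
#' @param age_at_diagnosis integer years, nonnegative
#' @return character vector of group labels
#' @export
recode_age_group <- function(age_at_diagnosis) {
  if (any(age_at_diagnosis < 0, na.rm = TRUE))
    stop("input error: negative age", call. = FALSE)
  cut(age_at_diagnosis, breaks = c(-1, 39, 49, 59, 69, 79, Inf),
      labels = age_group6_levels()) |> as.character()
}

#' Recode 17 regions into metropolitan / city / rural
#'
#' Deterministic lookup in a user-supplied mapping; used for released-cohort
#' reporting only (stratification uses the 17-level region).
#'
#' @param region17 region labels
#' @param mapping named character vector, all 17 labels as names
#' @return character vector of 3-level region labels
#' @export
recode_region <- function(region17, mapping = example_region3_mapping()) {
  unmapped <- setdiff(unique(region17[!is.na(region17)]), names(mapping))
  if (length(unmapped) > 0)
    stop("configuration error: unmapped region label(s): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  unname(mapping[region17])
}

stratum_key_vars <- function() {
  c("cancer_type", "diagnosis_year", "sex", "age_group6", "region17",
    "seer_stage")
}

#' Partition the eligible population into strata
#'
#' Strata are defined by cancer type, diagnosis year, sex, six-level age
#' group, 17-level region and SEER summary stage. Each stratum carries its
#' population size, the population mean of annual cost and the population
#' standard deviation (divide-by-N convention, since the sampler treats it
#' as the known population SD), plus its member ids and costs.
#'
#' @param eligible eligible patient table (no missing stratification fields)
#' @return tibble of stratum summaries, one row per stratum
#' @export
build_strata <- function(eligible) {
  if (nrow(eligible) == 0) {
    return(tibble::tibble(cancer_type = character(),
                          diagnosis_year = integer(), sex = character(),
                          age_group6 = character(), region17 = character(),
                          seer_stage = character(), stratum_id = character(),
                          N_h = integer(), pop_mean = double(),
                          sigma_h = double(), member_ids = list(),
                          member_costs = list()))
  }
  df <- dplyr::mutate(eligible,
                      age_group6 = recode_age_group(.data$age_at_diagnosis))
  strata <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(stratum_key_vars()))) |>
    dplyr::summarise(
      N_h = dplyr::n(),
      pop_mean = mean(.data$annual_cost_usd),
      sigma_h = sqrt(mean((.data$annual_cost_usd -
                             mean(.data$annual_cost_usd))^2)),
      member_ids = list(.data$patient_id),
      member_costs = list(.data$annual_cost_usd),
      .groups = "drop")
  strata$stratum_id <- do.call(paste,
                               c(strata[stratum_key_vars()], sep = "|"))
  dplyr::relocate(strata, "stratum_id", .after = "seer_stage")
}

#' Suppress small strata
#'
#' Strata below the minimum size are removed from the target population
#' entirely (their patients are not eligible for sampling), limiting
#' re-identification risk from rare covariate combinations.
#'
#' @param strata output of [build_strata()]
#' @param min_stratum_size smallest stratum size retained
#' @return list with `kept` strata, `suppressed` strata, and a `tally`
#'   (strata and patients suppressed)
#' @export
suppress_small_strata <- function(strata, min_stratum_size = 5L) {
  stopifnot(min_stratum_size >= 1)
  small <- strata$N_h < min_stratum_size
  list(kept = strata[!small, , drop = FALSE],
       suppressed = strata[small, , drop = FALSE],
       tally = tibble::tibble(n_strata_suppressed = sum(small),
                              n_patients_suppressed = sum(strata$N_h[small])))
}
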