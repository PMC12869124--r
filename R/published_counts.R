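# Published marginal counts and cost summaries for the four Korean cancer
# sample cohorts (stomach, breast, colorectal, liver; diagnoses 2012-2019).
# These are the printed population/sample tables of the data profile the
# cohorts were released with; they calibrate the synthetic generator and
# feed the descriptive-report arithmetic.

#' Published population and sample-cohort counts
#'
#' Long-format counts by age group, sex, region (3 groups), SEER summary
#' stage and incidence year, for the population and the released sample
#' cohort of each cancer type.
#'
#' @return tibble with columns `cancer_type`, `variable`, `level`,
#'   `population_n`, `sample_n`
#' @export
published_cohort_counts <- function() {
  row <- function(cancer, variable, levels, pop, smp) {
    tibble::tibble(cancer_type = cancer, variable = variable, level = levels,
                   population_n = pop, sample_n = smp)
  }
  ages <- age_group6_levels()
  stages <- seer_stage_levels()
  years <- as.character(2012:2019)
  reg3 <- c("metropolitan", "city", "rural")

  dplyr::bind_rows(
    ## stomach
    row("stomach", "age_group", ages,
        c(6741, 23547, 55963, 69168, 65297, 27387),
        c(1691, 5214, 11608, 14180, 13358, 5900)),
    row("stomach", "sex", c("male", "female"),
        c(167656, 80447), c(34542, 17409)),
    row("stomach", "region3", reg3,
        c(42244, 62976, 142883), c(8517, 13741, 29693)),
    row("stomach", "seer_stage", stages,
        c(10295, 150082, 48703, 25881, 13142),
        c(2360, 30346, 10440, 5976, 2829)),
    row("stomach", "year", years,
        c(31317, 31061, 30981, 30360, 31674, 31060, 30752, 30898),
        c(6456, 6447, 6505, 6381, 6648, 6545, 6479, 6490)),
    ## breast (females only)
    row("breast", "age_group", ages,
        c(20264, 66292, 58075, 30659, 13830, 3787),
        c(4178, 13321, 11714, 6329, 3024, 1020)),
    row("breast", "sex", "female", 192907, 39586),
    row("breast", "region3", reg3,
        c(43230, 50337, 99340), c(8611, 10607, 20368)),
    row("breast", "seer_stage", stages,
        c(29304, 95762, 54542, 8010, 5289),
        c(6035, 19280, 11151, 2011, 1109)),
    row("breast", "year", years,
        c(19263, 20268, 21400, 22502, 25722, 26477, 27852, 29423),
        c(3950, 4164, 4426, 4638, 5264, 5426, 5703, 6015)),
    ## colorectal
    row("colorectal", "age_group", ages,
        c(7178, 21895, 59277, 70920, 68748, 33273),
        c(1846, 4837, 12011, 14181, 13729, 6881)),
    row("colorectal", "sex", c("male", "female"),
        c(158209, 103082), c(31948, 21537)),
    row("colorectal", "region3", reg3,
        c(51546, 63939, 145806), c(10110, 13383, 29992)),
    row("colorectal", "seer_stage", stages,
        c(29193, 88999, 93026, 36349, 13724),
        c(6201, 18038, 18848, 7764, 2634)),
    row("colorectal", "year", years,
        c(31604, 31171, 31141, 31628, 33698, 33793, 33727, 34529),
        c(6393, 6332, 6402, 6495, 6901, 6942, 6913, 7107)),
    ## liver (no in-situ stage)
    row("liver", "age_group", ages,
        c(2418, 12192, 32870, 33084, 30083, 13677),
        c(724, 2942, 7026, 7042, 6439, 3202)),
    row("liver", "sex", c("male", "female"),
        c(93053, 31271), c(19821, 7554)),
    row("liver", "region3", reg3,
        c(20919, 32258, 71147), c(4275, 7367, 15733)),
    row("liver", "seer_stage", stages[-1],
        c(56618, 29937, 19255, 18514),
        c(11949, 6672, 4561, 4193)),
    row("liver", "year", years,
        c(15715, 15656, 15574, 15623, 15643, 15307, 15515, 15291),
        c(3400, 3413, 3433, 3451, 3466, 3390, 3430, 3392))
  )
}

#' Published medical-cost summaries by cancer type and age group
#'
#' Mean and standard deviation (USD, total medical costs in the incidence
#' year) for population and sample cohort; the population columns
#' parameterise the synthetic cost model.
#'
#' @return tibble with per-cell n, mean and SD for population and sample
#' @export
published_cost_summary <- function() {
  cell <- function(cancer, pn, pm, ps, sn, sm, ss) {
    tibble::tibble(cancer_type = cancer, age_group = age_group6_levels(),
                   population_n = pn, pop_mean = pm, pop_sd = ps,
                   sample_n = sn, sample_mean = sm, sample_sd = ss)
  }
  dplyr::bind_rows(
    cell("stomach",
         c(6741, 23547, 55963, 69168, 65297, 27387),
         c(9398, 7869, 8194, 8562, 9397, 9623),
         c(8320, 7588, 8401, 9849, 10511, 11504),
         c(1691, 5214, 11608, 14180, 13358, 5900),
         c(9604, 7893, 8188, 8588, 9270, 9672),
         c(7955, 7400, 7609, 9604, 9941, 11711)),
    cell("breast",
         c(20264, 66292, 58075, 30659, 13830, 3787),
         c(10380, 10074, 11297, 11501, 10999, 9487),
         c(7716, 7800, 9291, 9156, 10368, 13238),
         c(4178, 13321, 11714, 6329, 3024, 1020),
         c(10391, 10112, 11341, 11431, 10997, 9288),
         c(7725, 7801, 9381, 8577, 10521, 12448)),
    cell("colorectal",
         c(7178, 21895, 59277, 70920, 68748, 33273),
         c(9901, 10585, 10738, 11545, 12605, 12723),
         c(10971, 11147, 11741, 12005, 13067, 14438),
         c(1846, 4837, 12011, 14181, 13729, 6881),
         c(10014, 10421, 10570, 11394, 12425, 12474),
         c(11604, 10975, 11324, 11497, 12853, 13657)),
    cell("liver",
         c(2418, 12192, 32870, 33084, 30083, 13677),
         c(14030, 13581, 13558, 13327, 12372, 10197),
         c(13838, 16928, 15303, 15902, 11945, 10829),
         c(724, 2942, 7026, 7042, 6439, 3202),
         c(13765, 12923, 13316, 13218, 12421, 10133),
         c(13926, 15101, 14218, 18131, 11611, 11667))
  )
}
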