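test_that("rounding follows the round-half-up display convention", {
  expect_equal(round_half_up(20.85, 1), 20.9)
  expect_equal(round_half_up(2.05, 1), 2.1)
  expect_equal(round_half_up(25.04, 1), 25.0)
  expect_equal(round_half_up(-1.25, 1), -1.3)
})

test_that("published sampling fractions are reproduced from printed counts", {
  pub <- published_cohort_counts()
  totals <- pub |>
    dplyr::filter(variable == "age_group") |>
    dplyr::group_by(cancer_type) |>
    dplyr::summarise(pop = sum(population_n),
                     smp = sum(sample_n))
  t_st <- totals[totals$cancer_type == "stomach", ]
  expect_equal(t_st$pop, 248103)
  expect_equal(sampling_fraction(t_st$smp, t_st$pop), 20.9)
  t_lv <- totals[totals$cancer_type == "liver", ]
  expect_equal(sampling_fraction(t_lv$smp, t_lv$pop), 22.0)
  expect_equal(sampling_fraction(0, 100), 0.0)
  expect_error(sampling_fraction(1, 0), "positive")
})

test_that("age-group proportions match the published 60-plus figures", {
  pub <- published_cohort_counts()
  counts_of <- function(cc) {
    sub <- pub[pub$cancer_type == cc & pub$variable == "age_group", ]
    stats::setNames(sub$population_n, sub$level)
  }
  over60 <- c("60-69", "70-79", ">=80")
  expect_equal(age_group_proportion(counts_of("stomach"), over60), 65.2)
  expect_equal(age_group_proportion(counts_of("breast"), over60), 25.0)
  expect_equal(age_group_proportion(counts_of("stomach"),
                                    age_group6_levels()), 100.0)
  expect_error(age_group_proportion(stats::setNames(0, "0-39"), "0-39"),
               "zero total")
})

test_that("male-to-female ratios match the published rate ratios", {
  expect_equal(sex_rate_ratio(167656, 80447), 2.1)   # stomach population
  expect_equal(sex_rate_ratio(19821, 7554), 2.6)     # liver sample
  expect_equal(sex_rate_ratio(10, 10), 1.0)
  expect_error(sex_rate_ratio(5, 0), "positive")
})

test_that("per-cell sample percentages reproduce the printed table cells", {
  pub <- published_cohort_counts()
  cell <- pub[pub$cancer_type == "colorectal" & pub$level == ">=80", ]
  expect_equal(sampling_fraction(cell$sample_n, cell$population_n), 20.7)
  # every published cell is self-consistent under the same arithmetic
  pcts <- sampling_fraction(pub$sample_n, pub$population_n)
  expect_true(all(pcts > 19 & pcts < 31))
})

test_that("cost cells use the sample-SD reporting convention", {
  recs <- tibble::tibble(cancer_type = "stomach", age_at_diagnosis = 65L,
                         annual_cost_usd = c(100, 100))
  tab <- cost_summary_table(recs)
  expect_equal(tab$mean_cost, 100)
  expect_equal(tab$sd_cost, 0)

  recs2 <- tibble::tibble(cancer_type = "liver", age_at_diagnosis = 45L,
                          annual_cost_usd = c(0, 200))
  tab2 <- cost_summary_table(recs2)
  expect_equal(tab2$mean_cost, 100)
  expect_equal(tab2$sd_cost, sqrt(2) * 100, tolerance = 1e-9)
})

test_that("sampled cost means track population means within the FPC bands", {
  pl <- fixture_pipeline()
  ps <- pl$sampling$per_stratum
  ps$age_group <- pl$suppression$kept$age_group6[
    match(ps$stratum_id, pl$suppression$kept$stratum_id)]
  # the per-stratum guarantee |ybar_h - mu_h| <= half_h aggregates: in each
  # cancer-by-age cell, the n_h-weighted deviation of sample means from
  # population means is bounded by the n_h-weighted half-widths
  cells <- ps |>
    dplyr::group_by(cancer_type, age_group) |>
    dplyr::summarise(
      dev = abs(sum(final_n_h * (sample_mean - pop_mean))) /
        sum(final_n_h),
      bound = sum(final_n_h * (ci_high - sample_mean)) / sum(final_n_h),
      .groups = "drop")
  expect_true(all(cells$dev <= cells$bound + 1e-9))
  # and the cohort cell means reconstruct from the per-stratum samples
  smp_cells <- cost_summary_table(pl$cohort)
  rebuilt <- ps |>
    dplyr::group_by(cancer_type, age_group) |>
    dplyr::summarise(n = sum(final_n_h),
                     mean_cost = sum(final_n_h * sample_mean) /
                       sum(final_n_h), .groups = "drop")
  k <- dplyr::inner_join(smp_cells, rebuilt,
                         by = c("cancer_type", "age_group"))
  expect_equal(k$n.x, k$n.y)
  expect_equal(k$mean_cost.x, k$mean_cost.y, tolerance = 1e-9)
})

test_that("the pipeline runs end to end, deterministically", {
  pl <- fixture_pipeline()
  expect_true(all(pl$sampling$per_stratum$representative))
  expect_false(any(duplicated(pl$cohort$patient_id)))
  expect_true(all(pl$cohort$patient_id %in%
                    pl$exclusions$eligible$patient_id))
  expect_true(all(pl$summary_counts$pct >= 0 & pl$summary_counts$pct <= 100))
  # column sums reconcile with totals per cancer type
  by_var <- pl$summary_counts |>
    dplyr::group_by(cancer_type, variable) |>
    dplyr::summarise(pop = sum(population_n),
                     smp = sum(sample_n), .groups = "drop") |>
    dplyr::group_by(cancer_type) |>
    dplyr::summarise(ok = length(unique(pop)) == 1 &&
                       length(unique(smp)) == 1)
  expect_true(all(by_var$ok))

  pl2 <- run_pipeline(
    config = population_config(n_per_cancer = 1200, seed = 55),
    sampler = sampler_config(seed = 66))
  pl3 <- run_pipeline(
    config = population_config(n_per_cancer = 1200, seed = 55),
    sampler = sampler_config(seed = 66))
  expect_identical(pl2$cohort, pl3$cohort)
  expect_identical(pl2$summary_counts, pl3$summary_counts)
})

test_that("a census sampling rate returns the population with p = 1", {
  pl <- run_pipeline(
    config = population_config(n_per_cancer = 800, seed = 77),
    sampler = sampler_config(sampling_rate = 1.0, seed = 88))
  kept_ids <- unlist(pl$suppression$kept$member_ids)
  expect_setequal(pl$cohort$patient_id, kept_ids)
  expect_true(all(abs(pl$validation$per_stratum$p_value - 1) < 1e-9))
})
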