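#!/usr/bin/env Rscript
# Stage 5: descriptive tables and published-style arithmetic.
#
# Population/sample counts with percentages by stratification variable
# (region collapsed to metropolitan/city/rural for release-style
# reporting), cost summaries by cancer and age, and the printed-table
# arithmetic (sampling fractions, 60-plus proportions, male:female
# ratios) recomputed from the published counts.

library(stratcohort)

prep <- readRDS("scratch/prep.rds")
smp <- readRDS("scratch/sampling.rds")
target_pop <- prep$eligible[prep$eligible$patient_id %in%
                              unlist(prep$kept$member_ids), ]

counts <- summary_count_table(target_pop, smp$cohort,
                              example_region3_mapping())
write.csv(counts, "results/summary_counts.csv", row.names = FALSE)
write.csv(cost_summary_table(smp$cohort), "results/cost_summary_sample.csv",
          row.names = FALSE)
write.csv(cost_summary_table(target_pop),
          "results/cost_summary_population.csv", row.names = FALSE)

pub <- published_cohort_counts()
age <- function(cc) {
  s <- pub[pub$cancer_type == cc & pub$variable == "age_group", ]
  stats::setNames(s$population_n, s$level)
}
tots <- aggregate(cbind(population_n, sample_n) ~ cancer_type,
                  pub[pub$variable == "age_group", ], sum)
over60 <- c("60-69", "70-79", ">=80")
arith <- data.frame(
  quantity = c("sampling_fraction_stomach_pct",
               "sampling_fraction_liver_pct",
               "age60plus_stomach_pct", "age60plus_breast_pct",
               "male_female_ratio_stomach_population",
               "male_female_ratio_liver_sample"),
  value = c(
    sampling_fraction(tots$sample_n[tots$cancer_type == "stomach"],
                      tots$population_n[tots$cancer_type == "stomach"]),
    sampling_fraction(tots$sample_n[tots$cancer_type == "liver"],
                      tots$population_n[tots$cancer_type == "liver"]),
    age_group_proportion(age("stomach"), over60),
    age_group_proportion(age("breast"), over60),
    sex_rate_ratio(167656, 80447),
    sex_rate_ratio(19821, 7554)))
write.csv(arith, "results/published_arithmetic.csv", row.names = FALSE)

cat("published-table arithmetic:\n")
print(arith, row.names = FALSE)
cat("\nsimulated cohort cell percentages, range:",
    paste(range(counts$pct), collapse = " - "), "\n")
cat("tables written under results/\n")
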