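# Shared fixtures, built once per test run and memoised.

fixture_env <- new.env(parent = emptyenv())

# Moderate end-to-end pipeline run shared across test files.
fixture_pipeline <- function() {
  if (is.null(fixture_env$pipeline)) {
    fixture_env$pipeline <- run_pipeline(
      config = population_config(n_per_cancer = 6000, seed = 101),
      sampler = sampler_config(seed = 202))
  }
  fixture_env$pipeline
}

# A single stratum summary built from explicit costs, for sampler tests.
make_stratum <- function(costs, cancer = "stomach") {
  tibble::tibble(
    cancer_type = cancer, diagnosis_year = 2015L, sex = "male",
    age_group6 = "60-69", region17 = "Seoul", seer_stage = "localized",
    stratum_id = paste(cancer, "2015 male 60-69 Seoul localized", sep = "|"),
    N_h = length(costs), pop_mean = mean(costs),
    sigma_h = sqrt(mean((costs - mean(costs))^2)),
    member_ids = list(seq_along(costs)), member_costs = list(costs))
}

# Independent brute-force FPC half-width (direct formula arithmetic).
fpc_half_oracle <- function(sigma, N, n, z = 1.96) {
  if (n == N) 0 else z * sqrt((N - n) / (N - 1)) * sigma / sqrt(n)
}
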