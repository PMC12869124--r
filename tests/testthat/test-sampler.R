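test_that("FPC interval matches direct formula evaluation", {
  ci <- fpc_confidence_interval(50, 10, 100, 20, 1.96)
  expect_equal(ci$half_width, fpc_half_oracle(10, 100, 20), tolerance = 1e-12)
  expect_equal(ci$half_width, 3.9397, tolerance = 1e-4)
  expect_equal(c(ci$ci_low, ci$ci_high), c(46.060, 53.940), tolerance = 1e-4)

  census <- fpc_confidence_interval(50, 10, 100, 100)
  expect_equal(census$half_width, 0)
  constant <- fpc_confidence_interval(50, 0, 100, 20)
  expect_equal(c(constant$ci_low, constant$ci_high), c(50, 50))
  degenerate <- fpc_confidence_interval(5, 0, 1, 1)
  expect_equal(c(degenerate$ci_low, degenerate$ci_high), c(5, 5))
  expect_error(fpc_confidence_interval(50, 10, 100, 0), "at least 1")
  expect_error(fpc_confidence_interval(50, 10, 100, 101), "exceed")
})

test_that("FPC half-width is nonincreasing in n and zero at a census", {
  widths <- fpc_confidence_interval(0, 7.3, 57, 1:57)$half_width
  expect_true(all(diff(widths) <= 1e-12))
  expect_equal(widths[57], 0)
})

test_that("margin-of-error size agrees with a scan of the FPC oracle", {
  expect_equal(margin_of_error_size(100, 0, 500), 1L)
  expect_equal(margin_of_error_size(100, 10, 10000, 0.01, 1.96), 370L)
  expect_error(margin_of_error_size(0, 10, 100), "positive")

  # minimality against brute-force scan over n = 1..N
  cases <- list(c(mu = 100, sg = 10, N = 10000), c(100, 50, 300),
                c(80, 120, 2000), c(100, 1, 50))
  for (cs in cases) {
    d <- 0.01 * cs[1]
    n_star <- margin_of_error_size(cs[1], cs[2], cs[3])
    scan <- which(vapply(seq_len(cs[3]),
                         function(n) fpc_half_oracle(cs[2], cs[3], n) <= d,
                         logical(1)))[1]
    expect_equal(n_star, as.integer(scan))
    expect_lte(fpc_half_oracle(cs[2], cs[3], n_star), d)
    if (n_star > 1) expect_gt(fpc_half_oracle(cs[2], cs[3], n_star - 1), d)
  }
})

test_that("proportional allocation ceils and caps at the census", {
  expect_equal(allocate_sample_size(100, 0.20), 20L)
  expect_equal(allocate_sample_size(5, 0.20), 1L)
  expect_equal(allocate_sample_size(15, 0.20), 3L)  # no float-noise ceiling
  expect_equal(allocate_sample_size(6, 0.20), 2L)
  expect_equal(allocate_sample_size(123, 1.0), 123L)
  expect_equal(allocate_sample_size(1, 0.20), 1L)
})

test_that("candidate draws are SRSWOR, uniform over subsets", {
  st <- make_stratum(c(3, 1, 4, 1, 5))
  census <- draw_candidate(st, 5)
  expect_setequal(census$member_ids, 1:5)
  expect_true(census$representative)

  set.seed(99); c1 <- draw_candidate(st, 2)
  set.seed(99); c2 <- draw_candidate(st, 2)
  expect_identical(c1, c2)
  expect_error(draw_candidate(st, 6), "exceed")

  set.seed(100)
  draws <- replicate(10000, paste(sort(draw_candidate(st, 2)$member_ids),
                                  collapse = "-"))
  freq <- table(draws) / 10000
  expect_equal(length(freq), choose(5, 2))
  band <- 3 * sqrt(0.1 * 0.9 / 10000)
  expect_true(all(abs(freq - 0.1) < band))
})

test_that("a zero-variance stratum accepts its first candidate", {
  st <- make_stratum(rep(250, 40))
  set.seed(1)
  sel <- select_stratum_sample(st, sampler_config())
  expect_equal(sel$attempts, 1L)
  expect_equal(sel$n_h, 8L)
  expect_false(sel$augmented)
  expect_true(sel$representative)
})

test_that("accepted candidates always satisfy the representativeness criterion", {
  set.seed(17)
  for (rep_i in 1:20) {
    costs <- rlnorm(sample(5:30, 1), meanlog = 9, sdlog = 1)
    st <- make_stratum(costs)
    sel <- select_stratum_sample(st, sampler_config())
    half <- fpc_half_oracle(st$sigma_h, st$N_h, sel$n_h)
    expect_true(abs(sel$sample_mean - st$pop_mean) <= half + 1e-9)
    expect_true(sel$representative)
  }
})

test_that("closest-mean selection is confirmed by exhaustive enumeration", {
  # engineered stratum: only {0,100} pairs hit the population mean exactly
  costs <- c(0, 0, 0, 0, 100, 100, 100, 100)
  st <- make_stratum(costs)
  half2 <- fpc_half_oracle(st$sigma_h, st$N_h, 2)

  # enumeration oracle over all C(8,2) subsets: every pair is representative
  pairs <- utils::combn(8, 2)
  means <- apply(pairs, 2, function(ix) mean(costs[ix]))
  verdicts <- abs(means - st$pop_mean) <= half2
  expect_true(all(verdicts))
  expect_equal(sort(unique(means)), c(0, 50, 100))

  cfg <- sampler_config(always_best_of_k = TRUE)
  set.seed(21)
  sel <- select_stratum_sample(st, cfg)
  # best-of-50 must find a mean-50 pair (one {0} and one {100} member)
  expect_equal(sel$sample_mean, st$pop_mean)
  expect_setequal(costs[sel$member_ids] , c(0, 100))
  # accepted distance equals the minimum over the drawn candidates
  expect_equal(abs(sel$sample_mean - st$pop_mean),
               min(abs(sel$candidate_means[[1]] - st$pop_mean)))
})

test_that("enumeration reproduces representative flags on all small strata", {
  pop <- generate_population(population_config(n_per_cancer = 1500,
                                               seed = 61))
  elig <- apply_exclusions(pop)$eligible
  strata <- build_strata(elig)
  small <- strata[strata$N_h >= 5 & strata$N_h <= 12, ]
  small <- small[seq_len(min(25, nrow(small))), ]
  cfg <- sampler_config()
  for (h in seq_len(nrow(small))) {
    st <- small[h, ]
    n_h <- allocate_sample_size(st$N_h, cfg$sampling_rate)
    half <- fpc_half_oracle(st$sigma_h, st$N_h, n_h)
    subsets <- utils::combn(st$N_h, n_h)
    costs <- st$member_costs[[1]]
    or_means <- apply(subsets, 2, function(ix) mean(costs[ix]))
    or_flags <- abs(or_means - st$pop_mean) <= half

    # package verdict on each enumerated subset must match the oracle
    for (j in seq_len(ncol(subsets))) {
      m <- or_means[j]
      ci <- fpc_confidence_interval(m, st$sigma_h, st$N_h, n_h)
      expect_equal(st$pop_mean >= ci$ci_low && st$pop_mean <= ci$ci_high,
                   or_flags[j])
    }
    # and the accepted candidate is the closest among those it drew
    set.seed(1000 + h)
    sel <- select_stratum_sample(st, cfg)
    if (!sel$augmented) {
      drawn <- sel$candidate_means[[1]]
      rep_drawn <- drawn[abs(drawn - st$pop_mean) <= half + 1e-12]
      expect_equal(abs(sel$sample_mean - st$pop_mean),
                   min(abs(rep_drawn - st$pop_mean)))
    }
  }
})

test_that("closest-mean acceptance does not bias the sample mean", {
  set.seed(77)
  costs <- rlnorm(40, meanlog = 9, sdlog = 0.8)
  st <- make_stratum(costs)
  n_h <- allocate_sample_size(st$N_h, 0.2)
  cfg <- sampler_config()
  means <- vapply(1:1000, function(i) {
    set.seed(5000 + i)
    select_stratum_sample(st, cfg)$sample_mean
  }, numeric(1))
  se <- st$sigma_h / sqrt(n_h)
  expect_lt(abs(mean(means) - st$pop_mean), 0.5 * se)
})

test_that("cohort sampling composes strata deterministically", {
  expect_equal(length(sample_cohort(build_strata(
    generate_population(population_config(n_per_cancer = 0))))$cohort_ids), 0)

  pop <- generate_population(population_config(n_per_cancer = 2500,
                                               seed = 71))
  kept <- suppress_small_strata(build_strata(
    apply_exclusions(pop)$eligible), 5)$kept
  cfg <- sampler_config(seed = 8)
  r1 <- sample_cohort(kept, cfg)
  r2 <- sample_cohort(kept, cfg)
  expect_identical(r1$cohort_ids, r2$cohort_ids)
  expect_false(any(duplicated(r1$cohort_ids)))
  expect_true(all(r1$per_stratum$representative))

  # zero-variance strata: overall fraction is exactly the ceiling sum
  kz <- kept
  kz$member_costs <- lapply(kz$N_h, function(n) rep(100, n))
  kz$pop_mean <- 100; kz$sigma_h <- 0
  rz <- sample_cohort(kz, cfg)
  expect_equal(sum(rz$fractions$sample_n),
               sum(ceiling(0.2 * kz$N_h - 1e-9)))
  expect_true(all(rz$per_stratum$attempts == 1))
})

test_that("per-stratum substreams isolate strata from each other", {
  pop <- generate_population(population_config(n_per_cancer = 2500,
                                               seed = 72))
  kept <- suppress_small_strata(build_strata(
    apply_exclusions(pop)$eligible), 5)$kept
  cfg <- sampler_config(seed = 9)
  full <- sample_cohort(kept, cfg)
  drop_one <- sample_cohort(kept[-1, ], cfg)
  shared <- intersect(full$per_stratum$stratum_id,
                      drop_one$per_stratum$stratum_id)
  a <- full$per_stratum[match(shared, full$per_stratum$stratum_id), ]
  b <- drop_one$per_stratum[match(shared, drop_one$per_stratum$stratum_id), ]
  expect_identical(a$member_ids, b$member_ids)
})
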