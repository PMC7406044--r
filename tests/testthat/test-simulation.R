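test_that("allocation counts obey exact conservation", {
  rx <- randomness_experiment(n_units = 12, block_sizes = rep(3, 4),
                              n_sets = 400, seed = 3)
  for (m in rx$counts) {
    expect_true(all(rowSums(m) == 400))
    expect_true(all(colSums(m) == 400 * 3))
  }
  expect_error(randomness_experiment(10, c(4, 4)), "full-coverage")
  expect_error(randomness_experiment(10, c(6, 4)), "equal block sizes")
})

test_that("independent simulations are uncorrelated and well dispersed", {
  rx <- randomness_experiment(n_units = 24, block_sizes = rep(6, 4),
                              n_sets = 2000, seed = 8)
  g <- glance(rx)
  expect_equal(g$expected_count, 500)
  # loose 5-sigma-style sanity band around the binomial SD
  expect_gt(g$min_count_sd, 0.4 * g$binomial_sd)
  expect_lt(g$max_count_sd, 1.8 * g$binomial_sd)
  expect_true(all(tidy(rx)$p_value >= 0 & tidy(rx)$p_value <= 1))
  expect_lt(g$max_r_squared, 0.5)
})

test_that("coverage curves behave like nested search effort", {
  coh <- generate_cohort(n_units = 8, seed = 5,
                         covariates = list(a = c(6, 1.5), b = c(30, 4)))
  cc <- coverage_experiment(coh, c(4, 4), fractions = c(0.1, 0.3, 1),
                            replicates = 200, seed = 10)
  # exhaustive coverage always reaches the global minimum: 100% reduction
  last <- cc[cc$fraction == 1, ]
  expect_equal(last$mean_reduction, 100)
  expect_equal(last$sd_reduction, 0)
  expect_equal(last$mean_best, attr(cc, "global_min"))
  # best-found means improve with effort
  expect_true(all(diff(cc$mean_best) <= 1e-12))
  # identical seeds reproduce the curve bit for bit
  cc2 <- coverage_experiment(coh, c(4, 4), fractions = c(0.1, 0.3, 1),
                             replicates = 200, seed = 10)
  expect_identical(as.data.frame(cc), as.data.frame(cc2))
})

test_that("random search needs more attempts only near exhaustion", {
  coh <- generate_cohort(n_units = 8, seed = 5)
  cc <- coverage_experiment(coh, c(4, 4), fractions = c(0.06, 1),
                            replicates = 300, seed = 2)
  av <- attempts_vs_systematic(cc)
  # 6% coverage of 35 sets is ~2 draws: virtually duplicate-free
  expect_lt(av$excess_pct[1], 5)
  expect_false(av$material[1])
  # full coverage must redraw many duplicates (coupon-collector tail)
  expect_gt(av$mean_attempts[2], attr(cc, "total_unique"))
  expect_true(av$material[2])
})

test_that("engine searches match the hypergeometric miss law", {
  # real engine runs on an enumerable design: does a search of half the
  # sets miss all of the top 3?
  coh <- generate_cohort(n_units = 8, seed = 23,
                         covariates = list(a = c(5, 1.2), b = c(20, 3)))
  design <- validate_design(coh, block_design(c(4, 4)))
  enum <- blockbal:::enumerate_scores(coh, design)
  top3 <- vapply(
    enumerate_block_sets(coh, c(4, 4))[order(enum$scores)[1:3]],
    canonical_key, character(1))
  withr::local_seed(77)
  n_runs <- 400
  sampled <- 17
  misses <- sum(vapply(seq_len(n_runs), function(i) {
    res <- run_blocking(coh, design, target_unique = sampled)
    !any(top3 %in% tidy(res)$key)
  }, logical(1)))
  p <- top_k_miss_probability(35, sampled, 3)
  expect_lt(abs(misses / n_runs - p), 3 * sqrt(p * (1 - p) / n_runs))

  # and the closed form agrees with the index-sampling experiment
  mr <- miss_rate_experiment(35, sampled, 3, replicates = 4000, seed = 5)
  expect_lt(abs(mr$miss_rate - mr$expected),
            3 * sqrt(p * (1 - p) / 4000))
})
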