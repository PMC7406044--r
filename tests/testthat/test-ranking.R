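test_that("covariate summaries match hand arithmetic", {
  # one covariate with values 1..4; blocks {1,3} and {2,4}
  coh <- toy_cohort(c(1, 2, 3, 4))
  bs <- block_set(coh, list(coh$id[c(1, 3)], coh$id[c(2, 4)]))
  s <- summarize_covariates(coh, bs)
  expect_equal(s$block_means[[1]], c(2, 3))
  expect_equal(s$block_sds[[1]], c(sqrt(2), sqrt(2)))
  expect_equal(s$block_cvs[[1]], c(sqrt(2) / 2, sqrt(2) / 3))
  expect_equal(s$blockset_sd, sqrt(5 / 3))
  expect_equal(s$delta_mean_max, 1)
  expect_equal(s$delta_cv_max, sqrt(2) / 2 - sqrt(2) / 3)

  rv <- ranking_value(coh, bs)
  expect_equal(rv$ranking_value,
               1 / sqrt(5 / 3) + (sqrt(2) / 2 - sqrt(2) / 3),
               tolerance = 1e-12)
  expect_equal(rv$ranking_value, 1.010299, tolerance = 1e-6)
  expect_equal(glance(rv)$ranking_value, rv$ranking_value)
})

test_that("identical block multisets score exactly zero", {
  # both blocks hold the same covariate values
  coh <- toy_cohort(c(1, 1, 2, 2, 5, 5), c(9, 9, 7, 7, 4, 4))
  bs <- block_set(coh, list(coh$id[c(1, 3, 5)], coh$id[c(2, 4, 6)]))
  rv <- ranking_value(coh, bs)
  expect_identical(rv$ranking_value, 0)
  s <- tidy(rv)
  expect_equal(s$delta_mean_max, c(0, 0))
  expect_equal(s$delta_cv_max, c(0, 0))
})

test_that("the score is linear in the weights", {
  coh <- generate_cohort(seed = 31)
  bs <- sample_block_set(coh, block_design(c(8, 8)), seed = 1)
  base <- ranking_value(coh, bs,
                        block_design(c(8, 8), weights = c(1, 1, 1)))
  up <- ranking_value(coh, bs, block_design(c(8, 8), weights = c(2, 1, 1)))
  s <- tidy(base)
  contrib1 <- s$delta_mean_max[1] / s$blockset_sd[1] + s$delta_cv_max[1]
  expect_equal(up$ranking_value - base$ranking_value, contrib1,
               tolerance = 1e-12)
})

test_that("the score is invariant under positive rescaling of a covariate", {
  coh <- generate_cohort(seed = 17)
  design <- block_design(c(8, 8))
  withr::local_seed(2)
  for (i in 1:5) {
    bs <- sample_block_set(coh, design)
    v0 <- ranking_value(coh, bs, design)$ranking_value
    scaled <- as.data.frame(coh)
    scaled$cov2 <- scaled$cov2 * 7.3
    coh2 <- as_cohort(scaled, covariates = covariate_names(coh),
                      marker = "marker")
    expect_equal(ranking_value(coh2, bs, design)$ranking_value, v0,
                 tolerance = 1e-12)
    expect_gte(v0, 0)
  }
})

test_that("degenerate covariates follow the documented conventions", {
  # constant covariate: whole-set SD 0, all CVs 0, contributes 0
  coh <- toy_cohort(c(3, 3, 3, 3), c(1, 2, 3, 4))
  bs <- block_set(coh, list(coh$id[c(1, 2)], coh$id[c(3, 4)]))
  s <- summarize_covariates(coh, bs)
  expect_equal(s$blockset_sd[1], 0)
  expect_equal(s$block_cvs[[1]], c(0, 0))
  v <- ranking_value(coh, bs)$ranking_value
  expect_equal(v, oracle_ranking(coh, bs$blocks), tolerance = 1e-12)

  # singleton blocks have CV 0 by convention
  cs <- toy_cohort(c(1, 2, 6))
  bss <- block_set(cs, list(cs$id[1], cs$id[2:3]))
  expect_equal(summarize_covariates(cs, bss)$block_cvs[[1]][1], 0)

  # a block mean of exactly zero leaves the CV undefined
  cz <- toy_cohort(c(-1, 1, 2, 4))
  bz <- block_set(cz, list(cz$id[c(1, 2)], cz$id[c(3, 4)]))
  expect_error(ranking_value(cz, bz), "mean exactly 0")

  # negative means are allowed but flagged
  cn <- toy_cohort(c(-1, -3, -2, -4))
  bn <- block_set(cn, list(cn$id[c(1, 2)], cn$id[c(3, 4)]))
  expect_warning(summarize_covariates(cn, bn), "negative block mean")
})

test_that("sample and population SD conventions are both supported", {
  coh <- toy_cohort(c(1, 2, 3, 4))
  bs <- block_set(coh, list(coh$id[c(1, 3)], coh$id[c(2, 4)]))
  vs <- ranking_value(coh, bs, block_design(c(2, 2)))$ranking_value
  vp <- ranking_value(coh, bs,
                      block_design(c(2, 2),
                                   sd_type = "population"))$ranking_value
  expect_equal(vs, oracle_ranking(coh, bs$blocks, sd_type = "sample"),
               tolerance = 1e-12)
  expect_equal(vp, oracle_ranking(coh, bs$blocks, sd_type = "population"),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(vs, vp)))
})

test_that("scores match the independent scorer over a full enumeration", {
  coh <- generate_cohort(n_units = 8, seed = 23,
                         covariates = list(a = c(5, 1.2), b = c(20, 3)))
  design <- validate_design(coh, block_design(c(4, 4)))
  enum <- blockbal:::enumerate_scores(coh, design)
  brute <- vapply(enum$partitions, function(idx) {
    oracle_ranking(coh, lapply(idx, function(b) coh$id[b]))
  }, numeric(1))
  expect_lt(max(abs(enum$scores - brute)), 1e-12)
})
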