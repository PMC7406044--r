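test_that("a single all-covering block is the only outcome", {
  coh <- generate_cohort(n_units = 5, seed = 1)
  bs <- sample_block_set(coh, block_design(5), seed = 2)
  expect_setequal(bs$blocks[[1]], coh$id)
  expect_length(bs$leftover, 0)
})

test_that("block-set sampling is uniform over canonical outcomes", {
  coh <- generate_cohort(n_units = 4, seed = 3)
  design <- block_design(c(2, 2))
  n_draws <- 30000
  withr::local_seed(99)
  keys <- vapply(seq_len(n_draws), function(i) {
    canonical_key(sample_block_set(coh, design))
  }, character(1))
  counts <- table(keys)
  expect_length(counts, 3)  # the 3 unlabeled pairings of 4 units
  # each outcome within 3 binomial SDs of n/3
  p <- 1 / 3
  band <- 3 * sqrt(n_draws * p * (1 - p))
  expect_true(all(abs(counts - n_draws * p) <= band))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("canonical keys identify unlabeled partitions exactly", {
  coh <- generate_cohort(n_units = 7, seed = 4)
  id <- coh$id
  a <- block_set(coh, list(id[c(1, 2, 3)], id[c(4, 5)]))
  # order of units within a block is irrelevant
  b <- block_set(coh, list(id[c(3, 1, 2)], id[c(5, 4)]))
  expect_identical(canonical_key(a), canonical_key(b))
  # equal-size blocks are interchangeable
  c1 <- block_set(coh, list(id[c(1, 2)], id[c(3, 4)], id[c(5, 6, 7)]))
  c2 <- block_set(coh, list(id[c(3, 4)], id[c(1, 2)], id[c(5, 6, 7)]))
  expect_identical(canonical_key(c1), canonical_key(c2))
  # exchanging the contents of unequal-size blocks changes the partition
  d1 <- block_set(coh, list(id[c(1, 2)], id[c(3, 4, 5)]))
  d2 <- block_set(coh, list(id[c(3, 4)], id[c(1, 2, 5)]))
  expect_false(identical(canonical_key(d1), canonical_key(d2)))
  # the engine's internal key induces the same equivalence classes
  fast <- function(bs) {
    keyer <- blockbal:::make_keyer(7L, lengths(bs$blocks))
    keyer(match(c(unlist(bs$blocks), bs$leftover), coh$id))
  }
  expect_identical(fast(c1), fast(c2))
  expect_false(identical(fast(d1), fast(d2)))
})

test_that("the engine is deterministic and honours its stopping rules", {
  coh <- generate_cohort(seed = 5)
  design <- block_design(c(8, 8))
  one <- run_blocking(coh, design, target_unique = 1, seed = 7)
  expect_equal(nrow(tidy(one)), 1)
  expect_equal(glance(one)$unique_created, 1)

  r1 <- run_blocking(coh, design, target_unique = 300, seed = 11)
  r2 <- run_blocking(coh, design, target_unique = 300, seed = 11)
  expect_identical(tidy(r1), tidy(r2))
  g <- glance(r1)
  expect_equal(g$attempts, g$unique_created + g$duplicates_rejected)

  expect_warning(
    capped <- run_blocking(coh, design, target_unique = 6000,
                           max_attempts = 50, seed = 1),
    "attempt cap")
  expect_true(glance(capped)$cap_hit)
  expect_equal(glance(capped)$attempts, 50)
})

test_that("an exhaustive run reproduces the brute-force ranking exactly", {
  coh <- generate_cohort(n_units = 8, seed = 6,
                         covariates = list(a = c(10, 2), b = c(3, 1)))
  design <- block_design(c(4, 4))
  res <- run_blocking(coh, design, target_fraction = 1, seed = 13)
  expect_equal(glance(res)$unique_created, 35)

  sets <- enumerate_block_sets(coh, c(4, 4))
  expect_length(sets, 35)
  brute <- vapply(sets, function(bs) oracle_ranking(coh, bs$blocks),
                  numeric(1))
  lb <- tidy(res)
  expect_equal(lb$ranking_value, sort(brute), tolerance = 1e-12)
  # set-for-set: canonical keys agree in ranking order
  expect_identical(lb$key,
                   vapply(sets, canonical_key,
                          character(1))[order(brute)])
})

test_that("bounded leaderboards retain the k best and break ties by
           discovery order", {
  coh <- generate_cohort(n_units = 8, seed = 6,
                         covariates = list(a = c(10, 2), b = c(3, 1)))
  d10 <- block_design(c(4, 4), leaderboard_capacity = 10)
  res <- run_blocking(coh, d10, target_fraction = 1, seed = 21)
  brute <- vapply(enumerate_block_sets(coh, c(4, 4)),
                  function(bs) oracle_ranking(coh, bs$blocks), numeric(1))
  expect_equal(tidy(res)$ranking_value, sort(brute)[1:10],
               tolerance = 1e-12)

  # a constant covariate ranks every block set 0: ties everywhere, so the
  # leaderboard must hold the first-discovered sets in discovery order
  flat <- generate_cohort(n_units = 6, covariates = list(z = c(2, 0)),
                          markers = NULL, seed = 1)
  dflat <- block_design(c(2, 2), leaderboard_capacity = 5)
  full <- run_blocking(flat, dflat, target_fraction = 1, seed = 31)
  first5 <- run_blocking(flat, dflat, target_unique = 5, seed = 31)
  expect_equal(tidy(full)$ranking_value, rep(0, 5))
  expect_identical(tidy(full)$key, tidy(first5)$key)
})

test_that("leftover pools are tracked and never merged into blocks", {
  coh <- generate_cohort(n_units = 6, seed = 8)
  design <- block_design(c(2, 2))
  res <- run_blocking(coh, design, target_fraction = 1, seed = 9)
  # 45 unique sets (leftover pair distinct from the two blocks)
  expect_equal(glance(res)$unique_created, 45)
  bs <- best_block_set(res)
  expect_length(bs$leftover, 2)
  expect_setequal(c(unlist(bs$blocks), bs$leftover), coh$id)
})
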