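test_that("minimal re-marking solves the textbook cases exactly", {
  # two labels twice over: one of each per cage, nothing modified
  d0 <- minimal_remarking(c(a = "A", b = "A", c = "B", d = "B"), c(2, 2))
  expect_equal(d0$modifications, 0)
  expect_equal(sort(lengths(d0$subgroups)), c(2, 2))
  for (g in d0$subgroups) {
    kept <- setdiff(g, d0$modified)
    expect_equal(anyDuplicated(c("A", "B")[match(kept, letters[1:4])]), 0)
  }

  # one label four times: each cage keeps a single A
  d1 <- minimal_remarking(c(a = "A", b = "A", c = "A", d = "A"), c(2, 2))
  expect_equal(d1$modifications, 2)
  expect_equal(oracle_min_mods(rep("A", 4), c(2, 2)), 2)

  expect_error(minimal_remarking(c("A", "B"), c(2, 2)), "sum to 4")
})

test_that("returned divisions are consistent with the reported optimum", {
  withr::local_seed(42)
  for (i in 1:50) {
    size <- sample(2:8, 1)
    markers <- sample(LETTERS[1:sample(2:4, 1)], size, replace = TRUE)
    names(markers) <- sprintf("m%d", seq_len(size))
    shape <- oracle_random_shape(size)
    div <- minimal_remarking(markers, shape)
    expect_equal(sort(lengths(div$subgroups)), sort(shape))
    expect_setequal(unlist(div$subgroups), names(markers))
    # kept markers are unique within each subgroup
    for (g in div$subgroups) {
      kept <- setdiff(g, div$modified)
      expect_equal(anyDuplicated(markers[kept]), 0)
    }
    expect_equal(div$modifications, length(div$modified))
  }
})

test_that("the matching optimum equals exhaustive search on random blocks", {
  withr::local_seed(7)
  for (i in 1:300) {
    size <- sample(2:8, 1)
    markers <- sample(LETTERS[1:sample(2:4, 1)], size, replace = TRUE)
    shape <- oracle_random_shape(size)
    got <- minimal_remarking(markers, shape)$modifications
    expect_equal(got, oracle_min_mods_cached(markers, shape),
                 info = paste(paste(markers, collapse = ""), "/",
                              paste(shape, collapse = "+")))
    # each label keeps at most one unit per subgroup, so modifications
    # are at least sum(max(0, count - n_subgroups)); subgroup capacities
    # can force strictly more
    lb <- sum(pmax(0, table(markers) - length(shape)))
    expect_gte(got, lb)
  }
})

test_that("random subgrouping is uniform, seeded and unscored", {
  ids <- c("a", "b", "c", "d")
  one <- random_subgroups(ids, 4)
  expect_setequal(one$subgroups[[1]], ids)
  expect_true(is.na(one$modifications))

  expect_identical(random_subgroups(ids, c(2, 2), seed = 5),
                   random_subgroups(ids, c(2, 2), seed = 5))

  withr::local_seed(1)
  keys <- vapply(1:3000, function(i) {
    d <- random_subgroups(ids, c(2, 2))
    parts <- sort(vapply(d$subgroups,
                         function(g) paste(sort(g), collapse = ""),
                         character(1)))
    paste(parts, collapse = "|")
  }, character(1))
  counts <- table(keys)
  expect_length(counts, 3)
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("block-set totals add per-block optima", {
  mk <- c(rep("A", 4), rep("B", 4))
  coh <- toy_cohort(1:8, marker = mk)
  design <- block_design(c(4, 4), subgroup_sizes = c(2, 2))
  # blocks AAAA and BBBB: two modifications each
  bs <- block_set(coh, list(coh$id[1:4], coh$id[5:8]))
  expect_equal(total_modifications(coh, bs, design), 4)
  # interleaved blocks AABB: none
  bs2 <- block_set(coh, list(coh$id[c(1, 2, 5, 6)], coh$id[c(3, 4, 7, 8)]))
  expect_equal(total_modifications(coh, bs2, design), 0)
  # matches the brute-force per-block sum on a scrambled set
  bs3 <- block_set(coh, list(coh$id[c(1, 3, 5, 8)], coh$id[c(2, 4, 6, 7)]))
  brute <- sum(vapply(bs3$blocks, function(b) {
    oracle_min_mods(mk[match(b, coh$id)], c(2, 2))
  }, numeric(1)))
  expect_equal(total_modifications(coh, bs3, design), brute)

  expect_error(total_modifications(coh, bs, block_design(c(4, 4))),
               "no subgroups")
})
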