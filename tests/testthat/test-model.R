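test_that("cohort construction validates ids, covariates and markers", {
  df <- data.frame(id = c("m1", "m2", "m3"),
                   bw = c(21.5, 22.1, 20.8),
                   ear = c("L", "R", "L"))
  coh <- as_cohort(df, marker = "ear")
  expect_s3_class(coh, "cohort")
  expect_equal(covariate_names(coh), "bw")
  expect_true(has_markers(coh))

  expect_error(as_cohort(df[0, ]), "empty")
  expect_error(as_cohort(transform(df, id = c("m1", "m1", "m2"))),
               "duplicate unit id")
  expect_error(as_cohort(transform(df, bw = c(1, NA, 3))),
               "missing/non-finite")
  expect_error(as_cohort(df, covariates = "nope"), "not found")
  expect_error(as_cohort(transform(df, ear = c("L", NA, "R")),
                         marker = "ear"),
               "marker")
})

test_that("design validation enforces the feasibility invariants", {
  coh16 <- generate_cohort(seed = 1)
  # two blocks of 8 from 16 units with one weight per covariate is valid
  d <- validate_design(coh16, block_design(c(8, 8), weights = c(1, 1, 1)))
  expect_equal(d$weights, c(1, 1, 1))
  # and subgroups of 4+4 per block are valid too
  expect_no_error(validate_design(
    coh16, block_design(c(8, 8), subgroup_sizes = list(c(4, 4), c(4, 4)))))

  coh4 <- generate_cohort(n_units = 4, seed = 2)
  expect_error(validate_design(coh4, block_design(8)), "only 4 units")
  expect_error(validate_design(coh16, block_design(c(8, 8),
                                                   weights = c(1, 2))),
               "length 2")
  expect_error(block_design(c(8, 8), subgroup_sizes = list(c(4, 3), c(4, 4))),
               "sum to 7")
  # marker-based subgroups demand a marker column unless random is allowed
  no_mark <- generate_cohort(markers = NULL, seed = 3)
  d_sub <- block_design(c(8, 8), subgroup_sizes = c(4, 4),
                        subgroup_method = "markers")
  expect_error(validate_design(no_mark, d_sub), "no marker column")
  expect_no_error(validate_design(
    no_mark, block_design(c(8, 8), subgroup_sizes = c(4, 4))))
})

test_that("validate_design is idempotent", {
  coh <- generate_cohort(seed = 1)
  d1 <- validate_design(coh, block_design(c(8, 8)))
  expect_identical(validate_design(coh, d1), d1)
})

test_that("block sets round-trip through the tidy representation", {
  coh <- generate_cohort(n_units = 7, seed = 4)
  bs <- block_set(coh, list(coh$id[c(3, 1, 5)], coh$id[c(2, 6)]))
  expect_equal(sort(bs$leftover), sort(coh$id[c(4, 7)]))

  tb <- tibble::as_tibble(bs)
  rebuilt <- block_set(coh, split(tb$id[!is.na(tb$block)],
                                  tb$block[!is.na(tb$block)]))
  expect_identical(canonical_key(rebuilt), canonical_key(bs))

  expect_error(block_set(coh, list(coh$id[c(1, 1)], coh$id[2])), "disjoint")
  expect_error(block_set(coh, list("ghost")), "unknown unit id")
})
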