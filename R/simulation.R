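# Validation simulations: the allocation-randomness check and the
# rank-versus-search-coverage curves.

#' Allocation-randomness experiment
#'
#' Runs two independent simulations, each generating `n_sets` unique block
#' sets of a full-coverage equal-block design, and tallies how often every
#' unit lands in every block. Under truly random allocation each unit is
#' expected in each block `n_sets * b / n` times (exactly, on average, by
#' conservation), the across-unit spread of the counts is binomial, and the
#' per-unit counts of the two simulations are uncorrelated. The default
#' design divides 32 units into 4 blocks of 8 over 10,000 sets, so the
#' expected count is 2,500 per unit per block.
#'
#' @param n_units Cohort size; blocks must cover it exactly.
#' @param block_sizes Equal block sizes summing to `n_units`.
#' @param n_sets Number of unique block sets per simulation.
#' @param seed Optional integer seed covering both simulations.
#' @return An object of class `randomness_experiment`: `counts` (two
#'   unit-by-block allocation count matrices), `correlations` (tibble with
#'   one row per block: Pearson `r`, `r_squared`, `p_value` between the two
#'   simulations' per-unit counts), and the design parameters. `tidy()`
#'   returns the correlations; `glance()` the summary; `autoplot()` draws
#'   the per-block scatter.
#' @examples
#' rx <- randomness_experiment(n_sets = 500, seed = 1)
#' glance(rx)
#' @export
randomness_experiment <- function(n_units = 32,
                                  block_sizes = rep(8, 4),
                                  n_sets = 10000,
                                  seed = NULL) {
  n_units <- as.integer(n_units)
  block_sizes <- as.integer(block_sizes)
  if (sum(block_sizes) != n_units) {
    stop("the randomness experiment needs a full-coverage design ",
         "(blocks summing to n_units)", call. = FALSE)
  }
  if (length(unique(block_sizes)) != 1L) {
    stop("the randomness experiment needs equal block sizes", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  k <- length(block_sizes)
  ends <- cumsum(block_sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  slices <- lapply(seq_len(k), function(j) starts[j]:ends[j])
  keyer <- make_keyer(n_units, block_sizes)
  one_sim <- function() {
    counts <- matrix(0L, n_units, k,
                     dimnames = list(sprintf("u%02d", seq_len(n_units)),
                                     paste0("block", seq_len(k))))
    registry <- new.env(hash = TRUE, parent = emptyenv())
    made <- 0L
    while (made < n_sets) {
      perm <- sample.int(n_units)
      key <- keyer(perm)
      if (!is.null(registry[[key]])) next
      registry[[key]] <- TRUE
      made <- made + 1L
      for (j in seq_len(k)) {
        counts[perm[slices[[j]]], j] <- counts[perm[slices[[j]]], j] + 1L
      }
    }
    counts
  }
  c1 <- one_sim()
  c2 <- one_sim()
  correlations <- purrr::map_dfr(seq_len(k), function(j) {
    ct <- stats::cor.test(c1[, j], c2[, j])
    tibble::tibble(block = j,
                   r = unname(ct$estimate),
                   r_squared = unname(ct$estimate)^2,
                   p_value = ct$p.value)
  })
  structure(list(counts = list(c1, c2),
                 correlations = correlations,
                 n_units = n_units,
                 block_sizes = block_sizes,
                 n_sets = n_sets,
                 seed = seed),
            class = "randomness_experiment")
}

#' @rdname randomness_experiment
#' @param x A `randomness_experiment`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.randomness_experiment <- function(x, ...) x$correlations

#' @rdname randomness_experiment
#' @exportS3Method generics::glance
glance.randomness_experiment <- function(x, ...) {
  p <- x$block_sizes[1] / x$n_units
  tibble::tibble(
    n_units = x$n_units,
    n_blocks = length(x$block_sizes),
    n_sets = x$n_sets,
    expected_count = x$n_sets * p,
    binomial_sd = sqrt(x$n_sets * p * (1 - p)),
    min_count_sd = min(apply(x$counts[[1]], 2, stats::sd),
                       apply(x$counts[[2]], 2, stats::sd)),
    max_count_sd = max(apply(x$counts[[1]], 2, stats::sd),
                       apply(x$counts[[2]], 2, stats::sd)),
    max_r_squared = max(x$correlations$r_squared),
    min_p_value = min(x$correlations$p_value))
}

#' @export
print.randomness_experiment <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0(
    "Allocation-randomness experiment: %d units, %d blocks of %d, ",
    "2 x %d unique sets\n",
    "  expected count %g per unit per block; count SD range %.1f-%.1f ",
    "(binomial %.1f)\n",
    "  cross-simulation R^2 <= %.3f, smallest p = %.3f\n"),
    x$n_units, length(x$block_sizes), x$block_sizes[1], x$n_sets,
    g$expected_count, g$min_count_sd, g$max_count_sd, g$binomial_sd,
    g$max_r_squared, g$min_p_value))
  invisible(x)
}

# draw uniform set indices (1..total) until k are distinct; returns the
# number of draws and the best (minimal) score among the distinct sets.
# Distribution-identical to the engine's sample-and-reject loop, since the
# engine samples canonical block sets uniformly.
draw_until_k_distinct <- function(total, k, scores) {
  seen <- logical(total)
  found <- 0L
  attempts <- 0
  best <- Inf
  while (found < k) {
    est <- if (k < total) {
      total * log((total - found) / (total - k))
    } else {
      total * (log(total - found + 1) + 1)
    }
    m <- max(64L, ceiling(1.3 * est))
    x <- sample.int(total, m, replace = TRUE)
    new_first <- !seen[x] & !duplicated(x)
    cum_new <- cumsum(new_first)
    if (found + cum_new[m] >= k) {
      pos <- which(cum_new == k - found)[1]
      x <- x[seq_len(pos)]
      new_first <- new_first[seq_len(pos)]
      attempts <- attempts + pos
      found <- k
    } else {
      attempts <- attempts + m
      found <- found + cum_new[m]
    }
    seen[x[new_first]] <- TRUE
    best <- min(best, min(scores[x]))
  }
  list(attempts = attempts, best = best)
}

#' Search-coverage experiment
#'
#' Measures how the best ranking value found improves as a larger fraction
#' of all unique block sets is created. The design is first enumerated and
#' scored exhaustively (oracle for the global minimum and for the "fully
#' random" baseline, defined as the mean ranking value over all unique
#' sets — the expected score of a single random block set). Then, for each
#' coverage fraction `f`, `replicates` independent searches targeting
#' `ceiling(f * total)` unique sets are simulated and the lowest ranking
#' value found, the number of attempts (duplicates included), and the
#' fractional rank reduction `(baseline - best) / (baseline - global_min)`
#' are recorded. Searches are simulated by drawing uniform set indices with
#' rejection of duplicates, which is distribution-identical to
#' [run_blocking()]'s sampling loop.
#'
#' @inheritParams ranking_value
#' @param block_sizes Block sizes of the searched design.
#' @param fractions Coverage fractions in `(0, 1]`. The default grid is
#'   log-spaced and always includes 0.00093, 0.062 and 1.
#' @param replicates Independent searches per fraction (default 256).
#' @param seed Optional integer seed.
#' @param cap Maximum enumerable design size (default 1e5 unique sets).
#' @return A tibble of class `coverage_curve`, one row per fraction:
#'   `fraction`, `target_unique`, `replicates`, mean/SD of the lowest
#'   ranking value, of attempts, and of the percent reduction. Attributes
#'   `total_unique`, `global_min` and `baseline` carry the enumeration
#'   oracle. `autoplot()` draws the curve; see [attempts_vs_systematic()].
#' @examples
#' coh <- generate_cohort(n_units = 8, seed = 1)
#' coverage_experiment(coh, c(4, 4), fractions = c(0.2, 1),
#'                     replicates = 32, seed = 1)
#' @export
coverage_experiment <- function(cohort, block_sizes,
                                fractions = c(0.00031, 0.00093, 0.0031,
                                              0.0093, 0.031, 0.062, 0.125,
                                              0.25, 0.5, 1),
                                replicates = 256,
                                design = NULL,
                                seed = NULL,
                                cap = 1e5) {
  stopifnot(is_cohort(cohort))
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(design)) design <- block_design(block_sizes)
  enum <- enumerate_scores(cohort, design, cap = cap)
  scores <- enum$scores
  total <- length(scores)
  global_min <- min(scores)
  baseline <- mean(scores)
  if (!is.null(seed)) withr::local_seed(seed)
  rows <- purrr::map_dfr(fractions, function(f) {
    k <- min(ceiling(f * total), total)
    runs <- purrr::map(seq_len(replicates),
                       function(i) draw_until_k_distinct(total, k, scores))
    best <- vapply(runs, `[[`, numeric(1), "best")
    att <- vapply(runs, `[[`, numeric(1), "attempts")
    red <- 100 * (baseline - best) / (baseline - global_min)
    tibble::tibble(fraction = f,
                   target_unique = k,
                   replicates = replicates,
                   mean_best = mean(best),
                   sd_best = stats::sd(best),
                   mean_attempts = mean(att),
                   sd_attempts = stats::sd(att),
                   mean_reduction = mean(red),
                   sd_reduction = stats::sd(red))
  })
  structure(rows,
            total_unique = total,
            global_min = global_min,
            baseline = baseline,
            seed = seed,
            class = c("coverage_curve", class(rows)))
}

#' Random versus systematic search effort
#'
#' Compares, per coverage fraction, the mean number of attempts the random
#' search needed (duplicates included) with the attempt count of a
#' hypothetical systematic enumeration, which needs exactly
#' `ceiling(f * total)` steps. Random search only becomes materially more
#' expensive (flagged at >5% excess) near exhaustive coverage, where the
#' coupon-collector tail forces many duplicate redraws.
#'
#' @param curve A [coverage_experiment()] result.
#' @return A tibble: `fraction`, `systematic`, `mean_attempts`,
#'   `excess_pct`, and logical `material` (excess above 5%).
#' @export
attempts_vs_systematic <- function(curve) {
  stopifnot(inherits(curve, "coverage_curve"))
  dplyr::transmute(tibble::as_tibble(curve),
                   fraction = .data$fraction,
                   systematic = .data$target_unique,
                   mean_attempts = .data$mean_attempts,
                   excess_pct = 100 * (.data$mean_attempts /
                                         .data$systematic - 1),
                   material = .data$excess_pct > 5)
}

#' Empirical top-k miss-rate experiment
#'
#' Estimates, by repeated simulated searches, the probability that a search
#' creating `sampled` unique block sets misses all of the `k` best-balanced
#' sets, for comparison with the closed form
#' [top_k_miss_probability()]. Each replicate draws `sampled` distinct set
#' indices uniformly (the distribution of the engine's discovered sets) and
#' records whether none falls in the designated top `k`; by symmetry the
#' designated sets can be taken as indices `1..k`.
#'
#' @param total Total unique block sets of the design.
#' @param sampled Unique sets created per search.
#' @param k Size of the top set.
#' @param replicates Number of simulated searches (default 2000).
#' @param seed Optional integer seed.
#' @return A one-row tibble: `replicates`, `misses`, `miss_rate`, and the
#'   closed-form `expected` probability.
#' @examples
#' miss_rate_experiment(6435, 3218, 10, replicates = 200, seed = 1)
#' @export
miss_rate_experiment <- function(total, sampled, k, replicates = 2000,
                                 seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  misses <- sum(vapply(seq_len(replicates), function(i) {
    !any(sample.int(total, sampled) <= k)
  }, logical(1)))
  tibble::tibble(replicates = replicates,
                 misses = misses,
                 miss_rate = misses / replicates,
                 expected = top_k_miss_probability(total, sampled, k))
}
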