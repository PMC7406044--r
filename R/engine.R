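#' Draw one uniformly random block set
#'
#' Draws a uniform permutation of all unit ids (Fisher-Yates), fills the
#' blocks in declared order and sends the remainder to the leftover pool.
#' Because every unlabeled block set corresponds to the same number of
#' permutations (within-block orders, leftover orders and permutations of
#' equal-size blocks all have fixed counts), the induced distribution over
#' canonical block sets is exactly uniform.
#'
#' @inheritParams ranking_value
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return A [block_set()].
#' @export
sample_block_set <- function(cohort, design, seed = NULL) {
  design <- validate_design(cohort, design)
  if (!is.null(seed)) withr::local_seed(seed)
  n <- nrow(cohort)
  perm <- sample.int(n)
  ends <- cumsum(design$block_sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  blocks <- lapply(seq_along(ends),
                   function(j) cohort$id[perm[starts[j]:ends[j]]])
  leftover <- if (ends[length(ends)] < n) {
    cohort$id[perm[(ends[length(ends)] + 1L):n]]
  } else {
    character(0)
  }
  new_block_set(blocks, leftover)
}

#' Search for well-balanced block sets
#'
#' Repeatedly draws uniformly random block sets, rejects duplicates via a
#' canonical-key registry so each unique block set is scored once, ranks
#' accepted sets with [ranking_value()]'s balance score, and keeps the
#' best-balanced sets in a bounded leaderboard (default capacity 100,
#' lowest ranking value first; among equal values the earlier-discovered
#' set ranks first). When the design defines subgroups and the cohort
#' carries physical markers, the minimal number of marker modifications is
#' attached to every leaderboard entry.
#'
#' The search stops when the requested number of unique block sets has been
#' created, when every unique block set of the design has been found, or at
#' the attempt cap (rejected duplicates count as attempts but retry).
#'
#' @inheritParams ranking_value
#' @param target_unique Number of unique block sets to create; capped at
#'   the design's total.
#' @param target_fraction Alternative target as a fraction in `(0, 1]` of
#'   all unique block sets (e.g. `0.99` to find 99% of all combinations).
#' @param max_attempts Safety cap on total draws; defaults to 50 times the
#'   effective target (near-exhaustive searches redraw many duplicates). If
#'   hit before the target, a warning is raised and `glance()` reports
#'   `cap_hit = TRUE`.
#' @param seed Integer seed; identical seeds reproduce identical
#'   leaderboards bit for bit. Recorded in the result for audit.
#' @param progress_every Log a progress message every this many attempts
#'   (0, the default, disables logging).
#' @return An object of class `block_search`. `tidy()` returns the
#'   leaderboard (one row per retained block set: `rank`, `ranking_value`,
#'   `marker_modifications`, list-column `blocks`, canonical `key`);
#'   `glance()` returns the run statistics; `best_block_set()` extracts a
#'   leaderboard entry as a [block_set()]; `autoplot()` draws the
#'   leaderboard profile.
#' @examples
#' coh <- generate_cohort(seed = 1)
#' res <- run_blocking(coh, block_design(c(8, 8)),
#'                     target_unique = 500, seed = 42)
#' glance(res)
#' tidy(res)
#' best_block_set(res)
#' @export
run_blocking <- function(cohort, design,
                         target_unique = NULL,
                         target_fraction = NULL,
                         max_attempts = NULL,
                         seed = NULL,
                         progress_every = 0) {
  design <- validate_design(cohort, design)
  if (is.null(target_unique) && is.null(target_fraction)) {
    stop("set target_unique and/or target_fraction", call. = FALSE)
  }
  if (!is.null(target_fraction) &&
      (target_fraction <= 0 || target_fraction > 1)) {
    stop("target_fraction must be in (0, 1]", call. = FALSE)
  }
  n <- nrow(cohort)
  sizes <- design$block_sizes
  total_count <- count_unique_block_sets(n, sizes)
  total_num <- as.numeric(total_count)
  effective <- min(c(target_unique,
                     if (!is.null(target_fraction))
                       ceiling(target_fraction * total_num),
                     total_num))
  if (is.null(max_attempts)) max_attempts <- ceiling(50 * effective)

  X <- cohort_matrix(cohort)
  weights <- design$weights
  sd_type <- design$sd_type
  k <- length(sizes)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  slices <- lapply(seq_len(k), function(j) starts[j]:ends[j])
  covered <- ends[k]
  keyer <- make_keyer(n, sizes)
  sd_bs <- if (covered == n) col_sds(X, sd_type) else NULL
  if (any(X < 0)) {
    warning("cohort contains negative covariate values; block CVs keep ",
            "the sign of the mean", call. = FALSE)
  }

  mode <- subgroup_mode(cohort, design)
  marker_of <- if (mode == "markers") {
    stats::setNames(cohort$marker, cohort$id)
  }
  mod_cache <- new.env(hash = TRUE, parent = emptyenv())

  if (!is.null(seed)) withr::local_seed(seed)
  registry <- new.env(hash = TRUE, parent = emptyenv())
  capacity <- design$leaderboard_capacity
  vals <- numeric(0)
  entries <- list()
  attempts <- 0
  uniq <- 0
  dups <- 0

  while (uniq < effective && attempts < max_attempts) {
    attempts <- attempts + 1
    perm <- sample.int(n)
    key <- keyer(perm)
    if (!is.null(registry[[key]])) {
      dups <- dups + 1
      next
    }
    registry[[key]] <- TRUE
    uniq <- uniq + 1
    blocks_idx <- lapply(slices, function(s) perm[s])
    v <- score_blocks_idx(X, blocks_idx, weights, sd_type, sd_bs)
    if (length(vals) < capacity || v < vals[capacity]) {
      mods <- if (mode == "markers") {
        sum(vapply(seq_len(k), function(j) {
          min_modifications_cached(marker_of[cohort$id[blocks_idx[[j]]]],
                                   design$subgroup_sizes[[j]], mod_cache)
        }, integer(1)))
      } else if (mode == "random") {
        NA_integer_
      } else {
        NA_integer_
      }
      pos <- findInterval(v, vals)
      vals <- append(vals, v, after = pos)
      entries <- append(entries,
                        list(list(value = v, idx = blocks_idx, key = key,
                                  mods = mods)),
                        after = pos)
      if (length(vals) > capacity) {
        vals <- vals[seq_len(capacity)]
        entries <- entries[seq_len(capacity)]
      }
    }
    if (progress_every > 0 && attempts %% progress_every == 0) {
      message(sprintf("attempts %d | unique %d / %g | duplicates %d",
                      attempts, uniq, effective, dups))
    }
  }
  cap_hit <- uniq < effective
  if (cap_hit) {
    warning(sprintf(
      "attempt cap (%g) reached with %d of %g unique block sets created",
      max_attempts, uniq, effective), call. = FALSE)
  }

  blocks_ids <- lapply(entries, function(e) {
    lapply(e$idx, function(b) cohort$id[b])
  })
  leaderboard <- tibble::tibble(
    rank = seq_along(entries),
    ranking_value = vals,
    marker_modifications = vapply(entries, function(e) e$mods, integer(1)),
    blocks = blocks_ids,
    key = vapply(blocks_ids, function(bl) {
      canonical_key(new_block_set(
        bl, setdiff(cohort$id, unlist(bl, use.names = FALSE))))
    }, character(1)))
  if (mode == "none") {
    leaderboard$marker_modifications <- NULL
  }
  structure(list(leaderboard = leaderboard,
                 stats = list(attempts = attempts,
                              unique_created = uniq,
                              duplicates_rejected = dups,
                              cap_hit = cap_hit),
                 cohort = cohort,
                 design = design,
                 seed = seed,
                 subgroup_mode = mode,
                 total_unique = total_count,
                 effective_target = effective),
            class = "block_search")
}

#' @export
print.block_search <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0(
    "Block-set search: %d unique set(s) created (target %g, total %s)\n",
    "  attempts %d, duplicates rejected %d%s\n"),
    s$unique_created, x$effective_target, format(x$total_unique),
    s$attempts, s$duplicates_rejected,
    if (s$cap_hit) " [attempt cap reached]" else ""))
  if (nrow(x$leaderboard)) {
    cat(sprintf("  best ranking value: %.6g (leaderboard of %d)\n",
                x$leaderboard$ranking_value[1], nrow(x$leaderboard)))
  }
  invisible(x)
}

#' @rdname run_blocking
#' @param x A `block_search` result.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.block_search <- function(x, ...) x$leaderboard

#' @rdname run_blocking
#' @exportS3Method generics::glance
glance.block_search <- function(x, ...) {
  tibble::tibble(
    attempts = x$stats$attempts,
    unique_created = x$stats$unique_created,
    duplicates_rejected = x$stats$duplicates_rejected,
    cap_hit = x$stats$cap_hit,
    total_unique = as.numeric(x$total_unique),
    effective_target = x$effective_target,
    best_ranking_value = if (nrow(x$leaderboard))
      x$leaderboard$ranking_value[1] else NA_real_,
    leaderboard_size = nrow(x$leaderboard),
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed))
}

#' Extract a leaderboard entry as a block set
#'
#' @param result A [run_blocking()] result.
#' @param rank Leaderboard rank to extract (1 = best balanced).
#' @return A [block_set()].
#' @export
best_block_set <- function(result, rank = 1) {
  stopifnot(inherits(result, "block_search"))
  if (rank < 1 || rank > nrow(result$leaderboard)) {
    stop(sprintf("rank %s is outside the leaderboard (1..%d)",
                 rank, nrow(result$leaderboard)), call. = FALSE)
  }
  blocks <- result$leaderboard$blocks[[rank]]
  new_block_set(blocks,
                setdiff(result$cohort$id, unlist(blocks, use.names = FALSE)))
}
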