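#' Generate a synthetic cohort
#'
#' Draws a cohort of experimental units with independent normally
#' distributed covariates and an optional multiset of physical markers,
#' mirroring the kind of baseline table (body weight, plasma lipid levels,
#' ...) a rodent study would paste in. Defaults emulate a 16-mouse cohort
#' with three covariates on scales of roughly 4.4 +/- 1.7, 14.6 +/- 2.1 and
#' 1.2 +/- 0.35, carrying two ear-mark labels 8/8 — the worked-example
#' scale used throughout the package's tests and vignette.
#'
#' Normality is also the balance score's working assumption, so the
#' generator produces the data the method is designed for; real cohorts
#' with skewed or discrete covariates are not emulated.
#'
#' @param n_units Number of experimental units.
#' @param covariates Named list of `c(mean, sd)` pairs, one per covariate.
#'   An `sd` of 0 gives a constant covariate.
#' @param markers Character multiset of marker labels of length `n_units`
#'   (assigned in random order), label levels to recycle up to `n_units`,
#'   or `NULL` for a cohort without markers.
#' @param correlation Common pairwise correlation between covariates
#'   (default 0: independent draws).
#' @param seed Optional integer seed; a fixed seed reproduces the cohort
#'   exactly.
#' @return A [as_cohort()] cohort tibble with ids `u01`, `u02`, ...
#' @examples
#' generate_cohort(seed = 1)
#' generate_cohort(n_units = 6, covariates = list(bw = c(22, 2)),
#'                 markers = NULL, seed = 1)
#' @export
generate_cohort <- function(n_units = 16,
                            covariates = list(cov1 = c(4.4, 1.7),
                                              cov2 = c(14.6, 2.1),
                                              cov3 = c(1.2, 0.35)),
                            markers = c("L", "R"),
                            correlation = 0,
                            seed = NULL) {
  n_units <- as.integer(n_units)
  stopifnot(n_units >= 1L, is.list(covariates), length(covariates) >= 1L)
  if (is.null(names(covariates)) || any(!nzchar(names(covariates)))) {
    names(covariates) <- paste0("cov", seq_along(covariates))
  }
  bad <- lengths(covariates) != 2L
  if (any(bad)) {
    stop("each covariate spec must be c(mean, sd); offending: ",
         paste(names(covariates)[bad], collapse = ", "), call. = FALSE)
  }
  if (!is.null(markers)) {
    if (length(markers) < n_units) {
      markers <- rep(as.character(markers), length.out = n_units)
    } else if (length(markers) != n_units) {
      stop(sprintf("markers has length %d but the cohort has %d unit(s)",
                   length(markers), n_units), call. = FALSE)
    }
  }
  if (!is.null(seed)) withr::local_seed(seed)
  p <- length(covariates)
  z <- matrix(stats::rnorm(n_units * p), n_units, p)
  if (correlation != 0 && p > 1L) {
    sigma <- matrix(correlation, p, p)
    diag(sigma) <- 1
    z <- z %*% chol(sigma)
  }
  df <- tibble::tibble(id = sprintf("u%02d", seq_len(n_units)))
  for (i in seq_len(p)) {
    spec <- covariates[[i]]
    df[[names(covariates)[i]]] <- spec[1] + spec[2] * z[, i]
  }
  if (!is.null(markers)) {
    df$marker <- sample(as.character(markers))
    as_cohort(df, id = "id", covariates = names(covariates),
              marker = "marker")
  } else {
    as_cohort(df, id = "id", covariates = names(covariates))
  }
}

# every canonical partition of 1..n into blocks of `sizes` (+ leftover),
# as lists of integer index vectors; equal-size blocks are emitted in
# increasing order of their smallest element so each unlabeled block set
# appears exactly once
enum_partitions_idx <- function(n, sizes) {
  combos <- function(x, m) {
    if (length(x) == m) return(list(x))
    utils::combn(x, m, simplify = FALSE)
  }
  rec <- function(remaining, sizes, last_size, last_min) {
    if (!length(sizes)) return(list(list()))
    b <- sizes[1]
    out <- vector("list", 0L)
    for (cb in combos(remaining, b)) {
      if (b == last_size && cb[1] <= last_min) next
      subs <- rec(setdiff(remaining, cb), sizes[-1], b, cb[1])
      out <- c(out, lapply(subs, function(s) c(list(cb), s)))
    }
    out
  }
  rec(seq_len(as.integer(n)), as.integer(sizes), -1L, -1L)
}

#' Enumerate every unique block set of a design
#'
#' Systematic exhaustive enumeration of all canonical block sets — each
#' unlabeled partition exactly once. Intended as an oracle for small
#' designs (exhaustive scoring, global minima, coverage baselines); the
#' user-facing search is [run_blocking()].
#'
#' @inheritParams ranking_value
#' @param block_sizes Positive integers (or pass a [block_design()] via
#'   `design`).
#' @param cap Refuse to enumerate designs with more than this many unique
#'   block sets (default 1e6).
#' @return A list of [block_set()] objects of length
#'   `count_unique_block_sets(nrow(cohort), block_sizes)`.
#' @examples
#' coh <- generate_cohort(n_units = 4, seed = 1)
#' length(enumerate_block_sets(coh, c(2, 2))) # 3
#' @export
enumerate_block_sets <- function(cohort, block_sizes, cap = 1e6) {
  stopifnot(is_cohort(cohort))
  n <- nrow(cohort)
  total <- as.numeric(count_unique_block_sets(n, block_sizes))
  if (total > cap) {
    stop(sprintf("design has %g unique block sets, above the cap of %g",
                 total, cap), call. = FALSE)
  }
  parts <- enum_partitions_idx(n, block_sizes)
  lapply(parts, function(blocks_idx) {
    blocks <- lapply(blocks_idx, function(b) cohort$id[b])
    new_block_set(blocks,
                  cohort$id[setdiff(seq_len(n),
                                    unlist(blocks_idx, use.names = FALSE))])
  })
}

# exhaustively score a design: ranking value of every canonical block set
enumerate_scores <- function(cohort, design, cap = 1e6) {
  design <- validate_design(cohort, design)
  n <- nrow(cohort)
  total <- as.numeric(count_unique_block_sets(n, design$block_sizes))
  if (total > cap) {
    stop(sprintf("design has %g unique block sets, above the cap of %g",
                 total, cap), call. = FALSE)
  }
  parts <- enum_partitions_idx(n, design$block_sizes)
  X <- cohort_matrix(cohort)
  sd_bs <- if (sum(design$block_sizes) == n) col_sds(X, design$sd_type)
  scores <- vapply(parts, function(idx) {
    score_blocks_idx(X, idx, design$weights, design$sd_type, sd_bs)
  }, numeric(1))
  list(scores = scores, partitions = parts)
}
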