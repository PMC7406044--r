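#' Specify a block design
#'
#' A block design fixes the number and sizes of blocks, the per-covariate
#' weights entering the balance score, per-covariate display rounding, an
#' optional split of each block into housing subgroups, and the capacity of
#' the leaderboard kept during a search.
#'
#' @param block_sizes Positive integers, one per block (e.g. `c(8, 8)` for
#'   two blocks of eight). Sizes may sum to less than the cohort size; the
#'   surplus units form an explicit leftover pool that belongs to no block.
#' @param weights Non-negative covariate weights; either a single value
#'   recycled over all covariates (default 1) or one value per covariate.
#'   A larger weight makes imbalance in that covariate cost more.
#' @param decimals Non-negative integers controlling how covariate summaries
#'   are rounded in reports (single value or one per covariate). Display
#'   only: computation always uses full precision.
#' @param subgroup_sizes Optional split of each block into subgroups
#'   (cages): either a single integer vector applied to every block whose
#'   size matches its sum, or a list with one vector per block. Each vector
#'   must sum to the size of its block.
#' @param leaderboard_capacity Maximum number of best-balanced block sets
#'   retained during a search (default 100).
#' @param subgroup_method How subgroups are formed: `"auto"` uses physical
#'   markers when the cohort has them and random division otherwise;
#'   `"markers"` requires markers; `"random"` always divides at random.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`
#'   for all standard deviations entering the balance score.
#'
#' @return A list of class `block_design`.
#' @seealso [validate_design()], [run_blocking()]
#' @examples
#' block_design(c(8, 8), subgroup_sizes = c(4, 4))
#' @export
block_design <- function(block_sizes,
                         weights = 1,
                         decimals = 2,
                         subgroup_sizes = NULL,
                         leaderboard_capacity = 100,
                         subgroup_method = c("auto", "markers", "random"),
                         sd_type = c("sample", "population")) {
  subgroup_method <- match.arg(subgroup_method)
  sd_type <- match.arg(sd_type)
  block_sizes <- as.integer(block_sizes)
  if (length(block_sizes) == 0L || any(is.na(block_sizes)) ||
      any(block_sizes < 1L)) {
    stop("block_sizes must be positive integers", call. = FALSE)
  }
  if (any(weights < 0) || anyNA(weights)) {
    stop("weights must be non-negative", call. = FALSE)
  }
  if (any(decimals < 0) || anyNA(decimals)) {
    stop("decimals must be non-negative integers", call. = FALSE)
  }
  leaderboard_capacity <- as.integer(leaderboard_capacity)
  if (is.na(leaderboard_capacity) || leaderboard_capacity < 1L) {
    stop("leaderboard_capacity must be a positive integer", call. = FALSE)
  }
  if (!is.null(subgroup_sizes)) {
    if (!is.list(subgroup_sizes)) {
      subgroup_sizes <- rep(list(as.integer(subgroup_sizes)),
                            length(block_sizes))
    } else if (length(subgroup_sizes) != length(block_sizes)) {
      stop("subgroup_sizes must have one vector per block", call. = FALSE)
    } else {
      subgroup_sizes <- lapply(subgroup_sizes, as.integer)
    }
    for (j in seq_along(block_sizes)) {
      sg <- subgroup_sizes[[j]]
      if (any(sg < 1L) || anyNA(sg)) {
        stop("subgroup sizes must be positive integers", call. = FALSE)
      }
      if (sum(sg) != block_sizes[j]) {
        stop(sprintf(
          "subgroup sizes for block %d sum to %d but the block size is %d",
          j, sum(sg), block_sizes[j]), call. = FALSE)
      }
    }
  }
  structure(
    list(block_sizes = block_sizes,
         weights = as.double(weights),
         decimals = as.integer(decimals),
         subgroup_sizes = subgroup_sizes,
         leaderboard_capacity = leaderboard_capacity,
         subgroup_method = subgroup_method,
         sd_type = sd_type),
    class = "block_design")
}

#' Validate a block design against a cohort
#'
#' Checks that the design is feasible for the cohort: block sizes fit the
#' cohort, weight/decimal vectors match the covariate count, subgroup sizes
#' sum to their block sizes, and physical markers are available when
#' marker-based subgrouping is requested. Weights and decimals given as a
#' single value are expanded to one per covariate.
#'
#' Idempotent: validating an already-validated design returns it unchanged.
#'
#' @param cohort A [as_cohort()] cohort.
#' @param design A [block_design()].
#' @return The design, with `weights`/`decimals` expanded per covariate.
#' @export
validate_design <- function(cohort, design) {
  stopifnot(is_cohort(cohort), inherits(design, "block_design"))
  n <- nrow(cohort)
  p <- length(covariate_names(cohort))
  if (sum(design$block_sizes) > n) {
    stop(sprintf(
      "block sizes sum to %d but the cohort has only %d units",
      sum(design$block_sizes), n), call. = FALSE)
  }
  for (fld in c("weights", "decimals")) {
    v <- design[[fld]]
    if (length(v) == 1L) {
      design[[fld]] <- rep(v, p)
    } else if (length(v) != p) {
      stop(sprintf("%s has length %d but the cohort has %d covariate(s)",
                   fld, length(v), p), call. = FALSE)
    }
  }
  if (!is.null(design$subgroup_sizes)) {
    method <- design$subgroup_method
    if (method == "markers" && !has_markers(cohort)) {
      stop(paste("subgroups by physical marker requested but the cohort",
                 "has no marker column"), call. = FALSE)
    }
  }
  design
}

n_blocks <- function(design) length(design$block_sizes)

# resolved subgrouping mode for a cohort: "markers", "random" or "none"
subgroup_mode <- function(cohort, design) {
  if (is.null(design$subgroup_sizes)) return("none")
  switch(design$subgroup_method,
         markers = "markers",
         random = "random",
         auto = if (has_markers(cohort)) "markers" else "random")
}

#' @export
print.block_design <- function(x, ...) {
  cat("Block design:", paste(x$block_sizes, collapse = " + "),
      "units per block\n")
  if (!is.null(x$subgroup_sizes)) {
    cat("  subgroups:",
        paste(vapply(x$subgroup_sizes, paste, "", collapse = "+"),
              collapse = " | "),
        sprintf("(%s)\n", x$subgroup_method))
  }
  cat("  weights:", paste(x$weights, collapse = ", "),
      " leaderboard capacity:", x$leaderboard_capacity,
      " SD:", x$sd_type, "\n")
  invisible(x)
}
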