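#' Randomly allocate blocks to intervention groups
#'
#' Assigns the blocks of a chosen block set to named intervention groups by
#' a uniformly random bijection. Allocation never alters block membership;
#' it only decides which block receives which group label.
#'
#' @param block_set A [block_set()], typically [best_block_set()] of a
#'   search.
#' @param groups Character vector of distinct group labels, one per block.
#' @param seed Optional integer seed for a reproducible allocation.
#' @return A tibble of class `group_allocation` with one row per block:
#'   `block` (index), `group` (label) and `units` (list-column of unit
#'   ids). Use [unit_allocations()] for the long unit-to-group table.
#' @details Blocks of unequal size are allocated in exactly the same way (a
#'   design may intend unequal group sizes), but a warning reminds the user
#'   that the size-to-label pairing is then random.
#' @examples
#' coh <- generate_cohort(seed = 1)
#' bs <- sample_block_set(coh, block_design(c(8, 8)), seed = 2)
#' alloc <- allocate_groups(bs, c("vehicle", "treated"), seed = 7)
#' unit_allocations(alloc)
#' @export
allocate_groups <- function(block_set, groups, seed = NULL) {
  stopifnot(is_block_set(block_set))
  groups <- as.character(groups)
  k <- length(block_set$blocks)
  if (length(groups) != k) {
    stop(sprintf("%d group label(s) for %d block(s)", length(groups), k),
         call. = FALSE)
  }
  if (anyDuplicated(groups)) {
    stop("group labels must be distinct: ",
         paste(unique(groups[duplicated(groups)]), collapse = ", "),
         call. = FALSE)
  }
  sizes <- lengths(block_set$blocks)
  if (length(unique(sizes)) > 1L) {
    warning("blocks differ in size; the pairing of sizes with group ",
            "labels is random", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  out <- tibble::tibble(block = seq_len(k),
                        group = sample(groups),
                        units = block_set$blocks)
  class(out) <- c("group_allocation", class(out))
  out
}

#' Long unit-to-group table of an allocation
#'
#' @param allocation An [allocate_groups()] result.
#' @return A tibble with one row per blocked unit: `id`, `block`, `group`.
#'   Defined on exactly the blocked units; leftover units appear nowhere.
#' @export
unit_allocations <- function(allocation) {
  stopifnot(inherits(allocation, "group_allocation"))
  tidyr::unnest(
    dplyr::select(tibble::as_tibble(allocation),
                  "block", "group", id = "units"),
    "id")[, c("id", "block", "group")]
}
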