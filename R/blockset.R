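#' Block sets
#'
#' A block set is one division of (a subset of) the cohort into the designed
#' blocks: an ordered collection of blocks, each an unordered set of unit
#' ids, plus a leftover pool holding any unit assigned to no block. The
#' leftover pool is never interchangeable with a block, even when it happens
#' to match a block in size.
#'
#' @param cohort A [as_cohort()] cohort.
#' @param blocks A list of character vectors of unit ids, one per block.
#' @return An object of class `block_set` with elements `blocks` (list of
#'   character id vectors) and `leftover` (character vector).
#' @examples
#' coh <- generate_cohort(n_units = 6, seed = 1)
#' bs <- block_set(coh, list(coh$id[1:3], coh$id[4:6]))
#' canonical_key(bs)
#' @export
block_set <- function(cohort, blocks) {
  stopifnot(is_cohort(cohort), is.list(blocks))
  blocks <- lapply(blocks, as.character)
  all_ids <- unlist(blocks, use.names = FALSE)
  unknown <- setdiff(all_ids, cohort$id)
  if (length(unknown)) {
    stop("unknown unit id(s) in block set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(all_ids)) {
    stop("blocks are not disjoint: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "),
         call. = FALSE)
  }
  new_block_set(blocks, setdiff(cohort$id, all_ids))
}

new_block_set <- function(blocks, leftover) {
  structure(list(blocks = blocks, leftover = as.character(leftover)),
            class = "block_set")
}

#' @rdname block_set
#' @param x A `block_set`.
#' @export
is_block_set <- function(x) inherits(x, "block_set")

# check block sizes against a (validated) design
validate_block_set <- function(block_set, design) {
  sizes <- lengths(block_set$blocks)
  if (length(sizes) != length(design$block_sizes) ||
      any(sizes != design$block_sizes)) {
    stop(sprintf("block sizes (%s) do not match the design (%s)",
                 paste(sizes, collapse = ","),
                 paste(design$block_sizes, collapse = ",")), call. = FALSE)
  }
  invisible(block_set)
}

#' Canonical key of a block set
#'
#' Serializes a block set into a string that is invariant to the order of
#' units within a block and to permutation of equal-size blocks, so that two
#' block sets have equal keys if and only if they are the same unlabeled
#' partition. The leftover pool is appended as a distinguished terminal
#' segment and therefore never collides with a block. The search engine uses
#' these keys to reject duplicate block sets.
#'
#' @param block_set A [block_set()].
#' @return A single string.
#' @export
canonical_key <- function(block_set) {
  stopifnot(is_block_set(block_set))
  parts <- vapply(block_set$blocks,
                  function(b) paste(sort(b, method = "radix"), collapse = ","),
                  character(1))
  sizes <- lengths(block_set$blocks)
  parts <- parts[order(sizes, parts, method = "radix")]
  paste0(paste(parts, collapse = ";"), "#",
         paste(sort(block_set$leftover, method = "radix"), collapse = ","))
}

# Engine hot path: canonical key of the block set induced by a permutation.
#
# The key is the block-membership vector (unit -> block label, 0 for
# leftover) with labels canonicalized, inside each class of equal-size
# blocks, by order of first appearance. Membership is invariant to
# within-block order, and first-appearance relabeling makes it invariant
# to permutation of equal-size blocks, so keys are equal iff the unlabeled
# partitions are equal. Returns a closure to amortize design-level setup.
make_keyer <- function(n, sizes) {
  k <- length(sizes)
  covered <- sum(sizes)
  # position -> block label of the raw (declaration-order) filling;
  # positions past the blocks are leftover (label 0)
  labs <- rep.int(c(seq_len(k), 0L), c(sizes, n - covered))
  all_equal <- length(unique(sizes)) == 1L
  # labels available per size class, in fixed order
  class_of <- match(sizes, sort(unique(sizes)))
  class_labels <- split(seq_len(k), class_of)
  # canonical labels are emitted as single characters (codepoint 48 + label,
  # leftover = "0"), so the key is one n-character string
  map0 <- c(48L, integer(k))
  blk0 <- integer(n)
  function(perm) {
    blk <- blk0
    blk[perm] <- labs
    first_seen <- blk[!duplicated(blk)]
    first_seen <- first_seen[first_seen > 0L]
    if (all_equal) {
      map0[first_seen + 1L] <- 48L + seq_len(k)
    } else {
      cnt <- integer(length(class_labels))
      for (lab in first_seen) {
        cl <- class_of[lab]
        cnt[cl] <- cnt[cl] + 1L
        map0[lab + 1L] <- 48L + class_labels[[cl]][cnt[cl]]
      }
    }
    intToUtf8(map0[blk + 1L])
  }
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("Block set: %d block(s) (%s)%s\n",
              length(x$blocks),
              paste(lengths(x$blocks), collapse = " + "),
              if (length(x$leftover))
                sprintf(", %d leftover unit(s)", length(x$leftover))
              else ""))
  for (j in seq_along(x$blocks)) {
    cat(sprintf("  block %d: %s\n", j, paste(x$blocks[[j]], collapse = " ")))
  }
  if (length(x$leftover)) {
    cat("  leftover:", paste(x$leftover, collapse = " "), "\n")
  }
  invisible(x)
}

#' Tidy a block set into a unit-level tibble
#'
#' @param x A [block_set()].
#' @param ... Unused.
#' @return A tibble with columns `id` and `block` (integer block index, `NA`
#'   for leftover units). Round-trips: `block_set()` on the grouped ids
#'   reproduces the same canonical partition.
#' @exportS3Method tibble::as_tibble
as_tibble.block_set <- function(x, ...) {
  tibble::tibble(
    id = c(unlist(x$blocks, use.names = FALSE), x$leftover),
    block = c(rep.int(seq_along(x$blocks), lengths(x$blocks)),
              rep(NA_integer_, length(x$leftover))))
}
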