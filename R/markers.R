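# Physical-marker bookkeeping for within-block housing subgroups.
#
# Animals carry physical identity markers (ear clips, toe cuts) that must be
# unique within a home cage. When a block is split into housing subgroups,
# some animals may need their marker modified; modification causes
# discomfort, so the division that minimizes the number of modified animals
# is found exactly. Units are interchangeable within a marker label, so the
# optimum is a maximum flow on a small label-to-subgroup network:
# source -> label (capacity = label count), label -> subgroup (capacity 1:
# at most one *kept* marker of a label per cage), subgroup -> sink
# (capacity = subgroup size). The max flow is the number of units that can
# keep their marker.

max_kept_markers <- function(label_counts, subgroup_sizes) {
  n_lab <- length(label_counts)
  n_sub <- length(subgroup_sizes)
  src <- 1L
  snk <- 2L
  lab_v <- 2L + seq_len(n_lab)
  sub_v <- 2L + n_lab + seq_len(n_sub)
  edges <- c(rbind(src, lab_v),
             as.vector(t(as.matrix(expand.grid(lab_v, sub_v)))),
             rbind(sub_v, snk))
  caps <- c(label_counts, rep(1, n_lab * n_sub), subgroup_sizes)
  g <- igraph::make_graph(edges, n = 2L + n_lab + n_sub, directed = TRUE)
  fl <- igraph::max_flow(g, source = src, target = snk, capacity = caps)
  list(kept = as.integer(round(fl$value)),
       # flow on label->subgroup edges, as an n_lab x n_sub 0/1 matrix
       # (edge order is label-fastest, i.e. column-major)
       assignment = matrix(round(fl$flow[n_lab + seq_len(n_lab * n_sub)]),
                           nrow = n_lab))
}

#' Divide a block into subgroups with minimal marker re-marking
#'
#' Finds a division of a block into subgroups of the given sizes that
#' maximizes the number of units keeping their current physical marker,
#' subject to kept markers being unique within each subgroup. The number of
#' modifications is `block size - kept`, and the optimum is exact.
#'
#' @param markers Character vector of the block's marker labels, one per
#'   unit; names (if present) are used as unit ids.
#' @param subgroup_sizes Positive integers summing to `length(markers)`.
#' @return An object of class `subgroup_division`: `subgroups` (list of
#'   unit-id vectors), `modifications` (number of units that must be
#'   re-marked), `kept`, and `modified` (ids of units needing a new
#'   marker). Which replacement marker a modified unit should receive is
#'   left to the experimenter.
#' @examples
#' minimal_remarking(c(a = "L", b = "L", c = "R", d = "R"), c(2, 2))
#' @export
minimal_remarking <- function(markers, subgroup_sizes) {
  markers <- check_block_markers(markers, subgroup_sizes)
  subgroup_sizes <- as.integer(subgroup_sizes)
  ids <- names(markers)
  labels <- sort(unique(unname(markers)))
  counts <- as.integer(table(factor(markers, levels = labels)))
  sol <- max_kept_markers(counts, subgroup_sizes)
  # realize the flow as an explicit division
  pool <- split(ids, factor(unname(markers), levels = labels))
  subgroups <- vector("list", length(subgroup_sizes))
  kept_ids <- character(0)
  for (g in seq_along(subgroup_sizes)) {
    take <- character(0)
    for (l in seq_along(labels)) {
      if (sol$assignment[l, g] == 1L && length(pool[[l]])) {
        take <- c(take, pool[[l]][1])
        pool[[l]] <- pool[[l]][-1]
      }
    }
    subgroups[[g]] <- take
    kept_ids <- c(kept_ids, take)
  }
  # remaining units fill remaining capacity; they are the modified ones
  remaining <- unlist(pool, use.names = FALSE)
  for (g in seq_along(subgroup_sizes)) {
    need <- subgroup_sizes[g] - length(subgroups[[g]])
    if (need > 0L) {
      subgroups[[g]] <- c(subgroups[[g]], remaining[seq_len(need)])
      remaining <- remaining[-seq_len(need)]
    }
  }
  structure(list(subgroups = subgroups,
                 modifications = length(markers) - sol$kept,
                 kept = sol$kept,
                 modified = setdiff(ids, kept_ids)),
            class = "subgroup_division")
}

check_block_markers <- function(markers, subgroup_sizes) {
  if (sum(subgroup_sizes) != length(markers)) {
    stop(sprintf("subgroup sizes sum to %d but the block has %d unit(s)",
                 sum(subgroup_sizes), length(markers)), call. = FALSE)
  }
  markers <- as.character(markers) |> stats::setNames(names(markers))
  if (anyNA(markers) || any(!nzchar(markers))) {
    stop("every unit in the block must carry a marker", call. = FALSE)
  }
  if (is.null(names(markers))) {
    names(markers) <- as.character(seq_along(markers))
  }
  markers
}

#' Divide a block into subgroups at random
#'
#' Used when no physical markers are available: the block is divided
#' uniformly at random into subgroups of the given sizes. No modification
#' count applies (`modifications` is `NA`).
#'
#' @param block_ids Character vector of the block's unit ids.
#' @param subgroup_sizes Positive integers summing to `length(block_ids)`.
#' @param seed Optional integer seed for reproducibility.
#' @return A `subgroup_division` with `modifications = NA`.
#' @export
random_subgroups <- function(block_ids, subgroup_sizes, seed = NULL) {
  subgroup_sizes <- as.integer(subgroup_sizes)
  if (sum(subgroup_sizes) != length(block_ids)) {
    stop(sprintf("subgroup sizes sum to %d but the block has %d unit(s)",
                 sum(subgroup_sizes), length(block_ids)), call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  perm <- sample(block_ids)
  ends <- cumsum(subgroup_sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  subgroups <- lapply(seq_along(subgroup_sizes),
                      function(g) perm[starts[g]:ends[g]])
  structure(list(subgroups = subgroups,
                 modifications = NA_integer_,
                 kept = NA_integer_,
                 modified = character(0)),
            class = "subgroup_division")
}

#' @export
print.subgroup_division <- function(x, ...) {
  cat(sprintf("Subgroup division (%s): %s modification(s)\n",
              paste(lengths(x$subgroups), collapse = "+"),
              ifelse(is.na(x$modifications), "n/a", x$modifications)))
  for (g in seq_along(x$subgroups)) {
    cat(sprintf("  subgroup %d: %s\n", g,
                paste(x$subgroups[[g]], collapse = " ")))
  }
  invisible(x)
}

#' Total marker modifications of a block set
#'
#' Sums the minimal number of marker modifications over all blocks of a
#' block set, for the subgroup sizes of the design. This count is reported
#' beside the balance score (it never enters the score itself) so the
#' experimenter can prefer, among comparably balanced block sets, one that
#' spares animals re-marking.
#'
#' @inheritParams ranking_value
#' @return A non-negative integer.
#' @export
total_modifications <- function(cohort, block_set, design) {
  stopifnot(is_cohort(cohort), is_block_set(block_set))
  design <- validate_design(cohort, design)
  if (is.null(design$subgroup_sizes)) {
    stop("the design defines no subgroups", call. = FALSE)
  }
  if (!has_markers(cohort)) {
    stop("marker modifications need a cohort with physical markers",
         call. = FALSE)
  }
  validate_block_set(block_set, design)
  marker_of <- stats::setNames(cohort$marker, cohort$id)
  total <- 0L
  for (j in seq_along(block_set$blocks)) {
    ids <- block_set$blocks[[j]]
    div <- minimal_remarking(stats::setNames(marker_of[ids], ids),
                             design$subgroup_sizes[[j]])
    total <- total + div$modifications
  }
  total
}

# engine path: modification count only, memoized by the (label-count,
# subgroup-size) signature, which fully determines the optimum
min_modifications_cached <- function(markers, subgroup_sizes, cache) {
  counts <- sort(as.integer(table(markers)))
  key <- paste(paste(counts, collapse = ","),
               paste(subgroup_sizes, collapse = ","), sep = "|")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- length(markers) -
    max_kept_markers(counts, as.integer(subgroup_sizes))$kept
  cache[[key]] <- val
  val
}
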