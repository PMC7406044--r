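# Independent oracles, deliberately coded with plain base-R loops and
# stats::sd/mean rather than the package's vectorized internals.

# balance score of one block set (list of id vectors)
oracle_ranking <- function(cohort, blocks, weights = NULL,
                           sd_type = "sample") {
  X <- as.data.frame(cohort)[, covariate_names(cohort), drop = FALSE]
  p <- ncol(X)
  if (is.null(weights)) weights <- rep(1, p)
  sdf <- function(x) {
    if (length(x) < 2) return(0)
    if (sd_type == "sample") stats::sd(x) else sqrt(mean((x - mean(x))^2))
  }
  idx <- lapply(blocks, function(b) match(b, cohort$id))
  total <- 0
  for (i in seq_len(p)) {
    m <- vapply(idx, function(b) mean(X[b, i]), numeric(1))
    cv <- vapply(idx, function(b) sdf(X[b, i]) / mean(X[b, i]), numeric(1))
    sd_bs <- sdf(X[unlist(idx), i])
    mean_term <- if (sd_bs > 0) (max(m) - min(m)) / sd_bs else 0
    total <- total + (mean_term + (max(cv) - min(cv))) * weights[i]
  }
  total
}

# all labeled fillings of blocks of `sizes` from 1..n (leftover implicit)
oracle_labeled_fillings <- function(n, sizes) {
  rec <- function(rem, sizes) {
    if (!length(sizes)) return(list(list()))
    cb <- if (length(rem) == sizes[1]) list(rem) else {
      utils::combn(rem, sizes[1], simplify = FALSE)
    }
    out <- list()
    for (b in cb) {
      out <- c(out, lapply(rec(setdiff(rem, b), sizes[-1]),
                           function(s) c(list(b), s)))
    }
    out
  }
  rec(seq_len(n), as.integer(sizes))
}

# number of distinct unlabeled block sets, by canonicalizing every labeled
# filling (equal-size blocks interchangeable, leftover fixed)
oracle_count_block_sets <- function(n, sizes) {
  fillings <- oracle_labeled_fillings(n, sizes)
  keys <- vapply(fillings, function(bl) {
    parts <- vapply(bl, paste, character(1), collapse = ".")
    ord <- order(lengths(bl), parts)
    paste(parts[ord], collapse = "|")
  }, character(1))
  length(unique(keys))
}

# all divisions of ids into subgroups of `sizes` (labeled; enough for optima)
oracle_divisions <- function(ids, sizes) {
  rec <- function(rem, sizes) {
    if (!length(sizes)) return(list(list()))
    cb <- if (length(rem) == sizes[1]) list(rem) else {
      utils::combn(rem, sizes[1], simplify = FALSE)
    }
    out <- list()
    for (b in cb) {
      out <- c(out, lapply(rec(setdiff(rem, b), sizes[-1]),
                           function(s) c(list(b), s)))
    }
    out
  }
  rec(ids, as.integer(sizes))
}

# minimal re-markings by exhaustive search over all divisions
oracle_min_mods <- function(markers, sizes) {
  divs <- oracle_divisions(seq_along(markers), sizes)
  kept <- vapply(divs, function(dv) {
    sum(vapply(dv, function(g) length(unique(markers[g])), integer(1)))
  }, integer(1))
  length(markers) - max(kept)
}

# memoized on the (label-count, shape) signature that determines the optimum
oracle_min_mods_cached <- local({
  cache <- new.env(hash = TRUE, parent = emptyenv())
  function(markers, sizes) {
    key <- paste(paste(sort(as.integer(table(markers))), collapse = ","),
                 paste(sort(as.integer(sizes)), collapse = ","), sep = "|")
    v <- cache[[key]]
    if (is.null(v)) {
      v <- oracle_min_mods(markers, sizes)
      cache[[key]] <- v
    }
    v
  }
})

# random composition of `size` into 1-3 positive subgroup sizes
oracle_random_shape <- function(size) {
  k <- sample(seq_len(min(size, 3)), 1)
  if (k == 1) return(size)
  cuts <- sort(sample(seq_len(size - 1), k - 1))
  diff(c(0, cuts, size))
}

# tiny cohort with explicit covariate values (one covariate per vector)
toy_cohort <- function(..., marker = NULL) {
  covs <- list(...)
  n <- length(covs[[1]])
  df <- data.frame(id = sprintf("t%02d", seq_len(n)))
  for (i in seq_along(covs)) df[[paste0("x", i)]] <- covs[[i]]
  if (!is.null(marker)) {
    df$marker <- marker
    as_cohort(df, id = "id", covariates = paste0("x", seq_along(covs)),
              marker = "marker")
  } else {
    as_cohort(df, id = "id", covariates = paste0("x", seq_along(covs)))
  }
}
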