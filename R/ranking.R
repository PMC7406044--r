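#' Per-covariate balance summaries of a block set
#'
#' For each covariate this computes the block means, the block coefficients
#' of variation (CV, the block SD divided by the block mean, a dimensionless
#' proportion), the SD of the covariate over all blocked units (leftover
#' units excluded), and the two spread statistics that enter the balance
#' score: the maximal difference between block means and the maximal
#' difference between block CVs.
#'
#' @param cohort A [as_cohort()] cohort.
#' @param block_set A [block_set()] whose blocks are all non-empty.
#' @param sd_type `"sample"` (n-1, default) or `"population"` SDs.
#' @return A tibble with one row per covariate: `covariate`,
#'   `delta_mean_max`, `blockset_sd`, `delta_cv_max`, and list-columns
#'   `block_means`, `block_sds`, `block_cvs`.
#' @details A singleton block has CV 0 by convention. A block mean of
#'   exactly zero makes the CV undefined and is an error. Negative block
#'   means are allowed (the CV keeps the sign of the mean) but trigger a
#'   warning, since CVs of sign-changing data are hard to interpret.
#' @export
summarize_covariates <- function(cohort, block_set,
                                 sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is_cohort(cohort), is_block_set(block_set))
  if (any(lengths(block_set$blocks) == 0L)) {
    stop("every block must be non-empty", call. = FALSE)
  }
  X <- cohort_matrix(cohort)
  idx <- lapply(block_set$blocks, function(b) match(b, cohort$id))
  stats <- block_stats(X, idx, sd_type)
  if (any(stats$means < 0)) {
    warning("negative block mean(s); coefficients of variation keep the ",
            "sign of the mean", call. = FALSE)
  }
  union_idx <- unlist(idx, use.names = FALSE)
  sd_bs <- col_sds(X[union_idx, , drop = FALSE], sd_type)
  tibble::tibble(
    covariate = covariate_names(cohort),
    delta_mean_max = apply(stats$means, 2, max) - apply(stats$means, 2, min),
    blockset_sd = sd_bs,
    delta_cv_max = apply(stats$cvs, 2, max) - apply(stats$cvs, 2, min),
    block_means = lapply(seq_len(ncol(X)), function(i) stats$means[, i]),
    block_sds = lapply(seq_len(ncol(X)), function(i) stats$sds[, i]),
    block_cvs = lapply(seq_len(ncol(X)), function(i) stats$cvs[, i]))
}

# means/sds/cvs per (block, covariate); k x p matrices
block_stats <- function(X, idx, sd_type) {
  p <- ncol(X)
  k <- length(idx)
  means <- sds <- cvs <- matrix(0, k, p)
  for (j in seq_len(k)) {
    b <- idx[[j]]
    nb <- length(b)
    xb <- X[b, , drop = FALSE]
    m <- .colMeans(xb, nb, p)
    if (any(m == 0)) {
      stop("undefined CV: a block has mean exactly 0 for covariate '",
           colnames(X)[which(m == 0)[1]], "'", call. = FALSE)
    }
    means[j, ] <- m
    if (nb > 1L) {
      xc <- xb - rep(m, each = nb)
      denom <- if (sd_type == "sample") nb - 1L else nb
      sds[j, ] <- sqrt(.colSums(xc * xc, nb, p) / denom)
    }
    cvs[j, ] <- sds[j, ] / m
  }
  list(means = means, sds = sds, cvs = cvs)
}

col_sds <- function(x, sd_type) {
  n <- nrow(x)
  p <- ncol(x)
  m <- .colMeans(x, n, p)
  xc <- x - rep(m, each = n)
  denom <- if (sd_type == "sample") n - 1L else n
  sqrt(.colSums(xc * xc, n, p) / denom)
}

#' Score the covariate balance of a block set
#'
#' The balance ("ranking") value of a block set sums, over covariates, the
#' maximal between-block mean difference expressed as a proportion of the
#' whole-set SD, plus the maximal between-block difference in coefficient
#' of variation, multiplied by the covariate's weight:
#'
#' \deqn{R = \sum_i \left(\frac{\Delta \mathrm{Mean}_{max,i}}
#'   {\mathrm{SD}_{set,i}} + \Delta \mathrm{CV}_{max,i}\right) w_i}
#'
#' Lower is better balanced; the value is 0 exactly when every covariate has
#' identical block means and identical block CVs. When a covariate is
#' constant over the blocked units (whole-set SD 0) its mean term is 0: such
#' a covariate cannot distinguish any division.
#'
#' @inheritParams summarize_covariates
#' @param design A [block_design()]; defaults to equal weights and sample
#'   SDs. When the design defines subgroups, the minimal number of physical
#'   marker modifications is computed and attached (see
#'   [total_modifications()]).
#' @return An object of class `ranked_block_set`: the block set, its
#'   `ranking_value`, the per-covariate summary tibble, and (when subgroups
#'   are defined) `marker_modifications`. `tidy()` returns the summaries,
#'   `glance()` a one-row overview.
#' @examples
#' coh <- generate_cohort(seed = 1)
#' bs <- sample_block_set(coh, block_design(c(8, 8)), seed = 2)
#' ranking_value(coh, bs)
#' @export
ranking_value <- function(cohort, block_set, design = NULL) {
  stopifnot(is_cohort(cohort), is_block_set(block_set))
  if (is.null(design)) {
    design <- block_design(lengths(block_set$blocks))
  }
  design <- validate_design(cohort, design)
  validate_block_set(block_set, design)
  summ <- summarize_covariates(cohort, block_set, sd_type = design$sd_type)
  mean_term <- ifelse(summ$blockset_sd > 0,
                      summ$delta_mean_max / summ$blockset_sd, 0)
  value <- sum((mean_term + summ$delta_cv_max) * design$weights)
  mods <- switch(subgroup_mode(cohort, design),
                 markers = total_modifications(cohort, block_set, design),
                 random = NA_integer_,
                 none = NULL)
  structure(list(block_set = block_set,
                 ranking_value = value,
                 summaries = summ,
                 weights = design$weights,
                 marker_modifications = mods),
            class = "ranked_block_set")
}

#' @export
print.ranked_block_set <- function(x, ...) {
  cat(sprintf("Ranked block set: ranking value %.6g", x$ranking_value))
  if (!is.null(x$marker_modifications)) {
    cat(sprintf(", marker modifications %s",
                ifelse(is.na(x$marker_modifications), "n/a (random subgroups)",
                       x$marker_modifications)))
  }
  cat("\n")
  print(x$block_set)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname ranking_value
#' @param x A `ranked_block_set`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ranked_block_set <- function(x, ...) x$summaries

#' @rdname ranking_value
#' @exportS3Method generics::glance
glance.ranked_block_set <- function(x, ...) {
  tibble::tibble(
    ranking_value = x$ranking_value,
    marker_modifications =
      if (is.null(x$marker_modifications)) NA_integer_
      else x$marker_modifications,
    n_blocks = length(x$block_set$blocks),
    n_leftover = length(x$block_set$leftover))
}

# engine hot path: ranking value from integer block indices.
# sd_bs may be precomputed (full-coverage designs) or NULL to recompute.
score_blocks_idx <- function(X, idx, weights, sd_type, sd_bs = NULL) {
  p <- ncol(X)
  maxm <- minm <- maxcv <- mincv <- NULL
  for (b in idx) {
    nb <- length(b)
    xb <- X[b, , drop = FALSE]
    m <- .colMeans(xb, nb, p)
    if (any(m == 0)) {
      stop("undefined CV: a block has mean exactly 0 for covariate '",
           colnames(X)[which(m == 0)[1]], "'", call. = FALSE)
    }
    if (nb > 1L) {
      xc <- xb - rep(m, each = nb)
      denom <- if (sd_type == "sample") nb - 1L else nb
      cv <- sqrt(.colSums(xc * xc, nb, p) / denom) / m
    } else {
      cv <- numeric(p)
    }
    if (is.null(maxm)) {
      maxm <- minm <- m
      maxcv <- mincv <- cv
    } else {
      maxm <- pmax(maxm, m)
      minm <- pmin(minm, m)
      maxcv <- pmax(maxcv, cv)
      mincv <- pmin(mincv, cv)
    }
  }
  if (is.null(sd_bs)) {
    union_idx <- unlist(idx, use.names = FALSE)
    sd_bs <- col_sds(X[union_idx, , drop = FALSE], sd_type)
  }
  mean_term <- ifelse(sd_bs > 0, (maxm - minm) / sd_bs, 0)
  sum((mean_term + (maxcv - mincv)) * weights)
}
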