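#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot a search leaderboard
#'
#' Ranking value against leaderboard rank: a flat profile means many block
#' sets are about equally well balanced; a steep start means the best few
#' stand out.
#'
#' @param object A [run_blocking()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.block_search <- function(object, ...) {
  ggplot2::ggplot(object$leaderboard,
                  ggplot2::aes(.data$rank, .data$ranking_value)) +
    ggplot2::geom_step(colour = "grey50") +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::labs(x = "leaderboard rank", y = "ranking value",
                  title = sprintf("Best-balanced block sets (%d of %s unique)",
                                  object$stats$unique_created,
                                  format(object$total_unique,
                                         type = "scientific"))) +
    ggplot2::theme_minimal()
}

#' Plot per-block covariate balance of a block set
#'
#' One panel per covariate, units plotted by block with the block mean
#' marked, so imbalance in location or spread is visible at a glance.
#'
#' @param cohort A cohort.
#' @param block_set A [block_set()].
#' @return A ggplot.
#' @export
plot_block_balance <- function(cohort, block_set) {
  stopifnot(is_cohort(cohort), is_block_set(block_set))
  long <- tibble::as_tibble(block_set) |>
    dplyr::filter(!is.na(.data$block)) |>
    dplyr::left_join(tibble::as_tibble(cohort), by = "id") |>
    tidyr::pivot_longer(dplyr::all_of(covariate_names(cohort)),
                        names_to = "covariate", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$block), .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "red3") +
    ggplot2::facet_wrap(~covariate, scales = "free_y") +
    ggplot2::labs(x = "block", y = "covariate value") +
    ggplot2::theme_minimal()
}

#' Plot an allocation-randomness experiment
#'
#' Per block, each unit's allocation count in simulation 1 against its
#' count in simulation 2; random allocation shows a patternless cloud
#' around the expected count.
#'
#' @param object A [randomness_experiment()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.randomness_experiment <- function(object, ...) {
  k <- length(object$block_sizes)
  long <- purrr::map_dfr(seq_len(k), function(j) {
    tibble::tibble(block = paste("block", j),
                   sim1 = object$counts[[1]][, j],
                   sim2 = object$counts[[2]][, j])
  })
  expected <- object$n_sets * object$block_sizes[1] / object$n_units
  ggplot2::ggplot(long, ggplot2::aes(.data$sim1, .data$sim2)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.4, colour = "grey40",
                         linetype = "dashed") +
    ggplot2::geom_vline(xintercept = expected, colour = "red3",
                        linewidth = 0.2) +
    ggplot2::geom_hline(yintercept = expected, colour = "red3",
                        linewidth = 0.2) +
    ggplot2::facet_wrap(~block) +
    ggplot2::labs(x = "allocations, simulation 1",
                  y = "allocations, simulation 2") +
    ggplot2::theme_minimal()
}

#' Plot a search-coverage curve
#'
#' @param object A [coverage_experiment()] result.
#' @param type `"rank"` for the lowest ranking value found (mean +/- SD)
#'   against coverage fraction, `"attempts"` for random-search attempts
#'   against the systematic count.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.coverage_curve <- function(object, type = c("rank", "attempts"),
                                    ...) {
  type <- match.arg(type)
  tb <- tibble::as_tibble(object)
  if (type == "rank") {
    ggplot2::ggplot(tb, ggplot2::aes(.data$fraction, .data$mean_best)) +
      ggplot2::geom_ribbon(ggplot2::aes(
        ymin = .data$mean_best - .data$sd_best,
        ymax = .data$mean_best + .data$sd_best), alpha = 0.2) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = attr(object, "global_min"),
                          linetype = "dotted", colour = "red3") +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "fraction of unique block sets created",
                    y = "lowest ranking value (mean ± SD)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(tb, ggplot2::aes(.data$fraction)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$mean_attempts,
                                      colour = "random search")) +
      ggplot2::geom_point(ggplot2::aes(y = .data$mean_attempts,
                                       colour = "random search")) +
      ggplot2::geom_line(ggplot2::aes(y = .data$target_unique,
                                      colour = "systematic")) +
      ggplot2::scale_x_log10() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "fraction of unique block sets created",
                    y = "attempts", colour = NULL) +
      ggplot2::theme_minimal()
  }
}
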