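#' Read a cohort table from delimited text
#'
#' Reads a TSV (default) or CSV table with a header row, one row per
#' experimental unit, and builds a [as_cohort()] cohort. Columns are picked
#' by name, so the file's column order does not matter. Covariates are
#' parsed as reals with `.` as the decimal separator; a decimal comma is
#' also accepted whenever the field delimiter is not the comma itself, so
#' pastes from either spreadsheet locale parse identically.
#'
#' @param file Path to a delimited text file, or a literal string
#'   containing the table (detected by an embedded newline).
#' @param id Name of the unique-identifier column.
#' @param covariates Covariate column names in reporting order; defaults to
#'   every column other than `id` and `marker`.
#' @param marker Optional marker column name.
#' @param delimiter Field delimiter, `"\t"` by default.
#' @return A cohort tibble.
#' @examples
#' txt <- "id\tbw\tear\nm1\t21.3\tL\nm2\t22.8\tR\n"
#' read_cohort(txt, id = "id", marker = "ear")
#' @export
read_cohort <- function(file, id = "id", covariates = NULL, marker = NULL,
                        delimiter = "\t") {
  src <- if (length(file) == 1L && grepl("\n", file)) I(file) else file
  raw <- readr::read_delim(src, delim = delimiter,
                           col_types = readr::cols(
                             .default = readr::col_character()),
                           trim_ws = TRUE, progress = FALSE)
  if (nrow(raw) == 0L) {
    stop("cohort table is empty", call. = FALSE)
  }
  need <- c(id, covariates, marker)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("column(s) not found in cohort table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(covariates)) covariates <- setdiff(names(raw), c(id, marker))
  for (cv in covariates) {
    txt <- raw[[cv]]
    if (delimiter != ",") txt <- gsub(",", ".", txt, fixed = TRUE)
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric covariate value '%s' in column '%s', row %d",
        raw[[cv]][bad[1]], cv, bad[1]), call. = FALSE)
    }
    raw[[cv]] <- num
  }
  as_cohort(raw, id = id, covariates = covariates, marker = marker)
}

#' Write a cohort to delimited text
#'
#' Covariates are written with 17 significant digits, so
#' `read_cohort(write_cohort(x))` round-trips the cohort exactly (bit for
#' bit at full double precision).
#'
#' @param cohort A cohort.
#' @param file Output path.
#' @param delimiter Field delimiter, `"\t"` by default.
#' @return `file`, invisibly.
#' @export
write_cohort <- function(cohort, file, delimiter = "\t") {
  stopifnot(is_cohort(cohort))
  out <- tibble::as_tibble(cohort)
  for (cv in covariate_names(cohort)) {
    out[[cv]] <- sprintf("%.17g", out[[cv]])
  }
  readr::write_delim(out, file, delim = delimiter)
  invisible(file)
}

fmt_mean_sd <- function(m, s, decimals) {
  sprintf("%.*f±%.*f", decimals, m, decimals, s)
}

#' Write the search report
#'
#' Writes two files describing a [run_blocking()] leaderboard: a
#' machine-readable TSV (one row per ranked block set: rank, ranking value
#' at full precision and display-rounded, marker modifications where
#' applicable, per-block unit ids, canonical key) and a human-readable text
#' summary showing, per ranked set and block, the unit composition, the
#' subgroup composition where subgroups are defined, and each covariate's
#' mean and SD rounded to the design's `decimals`.
#'
#' @param result A `block_search` from [run_blocking()] with a non-empty
#'   leaderboard.
#' @param dir Output directory (created if missing).
#' @param name Base name of the two files (default `"blocking"`).
#' @param top Number of leaderboard entries detailed in the text summary
#'   (default: all).
#' @return Invisibly, a named character vector with the two paths.
#' @export
write_report <- function(result, dir, name = "blocking", top = Inf) {
  stopifnot(inherits(result, "block_search"))
  lb <- result$leaderboard
  if (nrow(lb) == 0L) {
    stop("leaderboard is empty; nothing to report", call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort <- result$cohort
  design <- result$design
  tsv_path <- file.path(dir, paste0(name, "_leaderboard.tsv"))
  txt_path <- file.path(dir, paste0(name, "_report.txt"))

  tab <- tibble::tibble(
    rank = lb$rank,
    ranking_value = sprintf("%.17g", lb$ranking_value),
    ranking_value_display = sprintf("%.*f", max(design$decimals),
                                    lb$ranking_value))
  if ("marker_modifications" %in% names(lb)) {
    tab$marker_modifications <- lb$marker_modifications
  }
  for (j in seq_along(design$block_sizes)) {
    tab[[paste0("block_", j)]] <- vapply(
      lb$blocks, function(bl) paste(bl[[j]], collapse = ","), character(1))
  }
  tab$key <- lb$key
  readr::write_tsv(tab, tsv_path)

  X <- cohort_matrix(cohort)
  marker_of <- if (has_markers(cohort)) {
    stats::setNames(cohort$marker, cohort$id)
  }
  mode <- result$subgroup_mode
  con <- file(txt_path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  s <- result$stats
  w("Covariate-balanced block randomization report")
  w("cohort: %d units, covariates: %s", nrow(cohort),
    paste(covariate_names(cohort), collapse = ", "))
  w("design: blocks of (%s); weights (%s); SD type: %s",
    paste(design$block_sizes, collapse = ", "),
    paste(design$weights, collapse = ", "), design$sd_type)
  w("search: %d attempts, %d unique sets, %d duplicates rejected; seed: %s",
    s$attempts, s$unique_created, s$duplicates_rejected,
    if (is.null(result$seed)) "none" else as.character(result$seed))
  w("total unique block sets of the design: %s", format(result$total_unique))
  n_detail <- min(top, nrow(lb))
  for (r in seq_len(n_detail)) {
    w("")
    w("== rank %d: ranking value %.17g (%s)%s", r, lb$ranking_value[r],
      sprintf("%.*f", max(design$decimals), lb$ranking_value[r]),
      if ("marker_modifications" %in% names(lb)) {
        sprintf(", marker modifications %s",
                ifelse(is.na(lb$marker_modifications[r]), "n/a",
                       lb$marker_modifications[r]))
      } else "")
    blocks <- lb$blocks[[r]]
    for (j in seq_along(blocks)) {
      ids <- blocks[[j]]
      idx <- match(ids, cohort$id)
      w("  block %d (n=%d): %s", j, length(ids), paste(ids, collapse = " "))
      if (!is.null(design$subgroup_sizes)) {
        div <- if (mode == "markers") {
          minimal_remarking(stats::setNames(marker_of[ids], ids),
                            design$subgroup_sizes[[j]])
        } else {
          random_subgroups(ids, design$subgroup_sizes[[j]])
        }
        for (g in seq_along(div$subgroups)) {
          w("    subgroup %d: %s", g,
            paste(div$subgroups[[g]], collapse = " "))
        }
        if (!is.na(div$modifications)) {
          w("    marker modifications in block: %d", div$modifications)
        }
      }
      for (i in seq_along(covariate_names(cohort))) {
        x <- X[idx, i]
        w("    %s: %s", covariate_names(cohort)[i],
          fmt_mean_sd(mean(x),
                      if (length(x) > 1) block_sd(x, design$sd_type) else 0,
                      design$decimals[i]))
      }
    }
  }
  invisible(c(leaderboard = tsv_path, report = txt_path))
}

block_sd <- function(x, sd_type) {
  if (sd_type == "sample") stats::sd(x)
  else sqrt(mean((x - mean(x))^2))
}
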