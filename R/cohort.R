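#' Construct a cohort of experimental units
#'
#' A cohort is a tibble with one row per experimental unit: a unique `id`
#' column, one or more numeric baseline covariate columns, and optionally a
#' `marker` column holding a categorical physical-marker label (ear mark,
#' toe cut, ...). All downstream functions (`run_blocking()`,
#' `ranking_value()`, `allocate_groups()`, ...) take a cohort as their first
#' argument.
#'
#' @param data A data frame with one row per experimental unit.
#' @param id Name of the column holding unique unit identifiers.
#' @param covariates Character vector of covariate column names, in the
#'   order they should be reported. Defaults to every numeric column that is
#'   neither `id` nor `marker`.
#' @param marker Optional name of a column with physical-marker labels.
#'
#' @return A tibble of class `cohort` with columns `id` (character), the
#'   covariates (double) and, when supplied, `marker` (character). Covariate
#'   names are recorded in the `"covariates"` attribute.
#'
#' @details Missing covariate values are a hard error: the balance score has
#'   no defined behaviour for incomplete baseline data. Covariates are kept
#'   at full floating precision throughout; the `decimals` setting of a
#'   [block_design()] only affects report formatting.
#'
#' @examples
#' df <- data.frame(mouse = paste0("m", 1:4),
#'                  weight = c(21.3, 22.8, 20.9, 23.4),
#'                  ear = c("L", "R", "L", "R"))
#' coh <- as_cohort(df, id = "mouse", marker = "ear")
#' covariate_names(coh)
#' @export
as_cohort <- function(data, id = "id", covariates = NULL, marker = NULL) {
  data <- as.data.frame(data)
  if (nrow(data) == 0L) {
    stop("cohort table is empty", call. = FALSE)
  }
  need <- c(id, covariates, marker)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("column(s) not found in cohort table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ids <- as.character(data[[id]])
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("unit ids must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate unit id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(covariates)) {
    candidates <- setdiff(names(data), c(id, marker))
    covariates <- candidates[vapply(data[candidates], is.numeric, logical(1))]
  }
  if (length(covariates) == 0L) {
    stop("cohort needs at least one numeric covariate column", call. = FALSE)
  }
  for (cv in covariates) {
    x <- data[[cv]]
    if (!is.numeric(x)) {
      stop("covariate column '", cv, "' is not numeric", call. = FALSE)
    }
    if (anyNA(x) || any(!is.finite(x))) {
      bad <- which(!is.finite(x))
      stop("missing/non-finite covariate value in column '", cv,
           "', row(s) ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  out <- tibble::tibble(id = ids)
  for (cv in covariates) out[[cv]] <- as.double(data[[cv]])
  if (!is.null(marker)) {
    mk <- as.character(data[[marker]])
    if (anyNA(mk) || any(!nzchar(mk))) {
      stop("every unit must carry a marker when a marker column is given",
           call. = FALSE)
    }
    out[["marker"]] <- mk
  }
  new_cohort(out, covariates)
}

new_cohort <- function(tbl, covariates) {
  structure(tbl,
            covariates = covariates,
            class = c("cohort", class(tibble::tibble())))
}

#' @rdname as_cohort
#' @param x A cohort.
#' @export
is_cohort <- function(x) inherits(x, "cohort")

#' @rdname as_cohort
#' @export
covariate_names <- function(x) {
  stopifnot(is_cohort(x))
  attr(x, "covariates")
}

#' @rdname as_cohort
#' @export
has_markers <- function(x) {
  stopifnot(is_cohort(x))
  "marker" %in% names(x)
}

# n x p matrix of covariate values, rows in cohort order
cohort_matrix <- function(cohort) {
  as.matrix(cohort[, covariate_names(cohort), drop = FALSE])
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("# A cohort: %d experimental units, %d covariate(s)%s\n",
              nrow(x), length(covariate_names(x)),
              if (has_markers(x)) ", with physical markers" else ""))
  NextMethod()
}
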