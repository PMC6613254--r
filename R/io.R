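#' Read a wide CSV of person-level scale scores
#'
#' Reads a CSV with one row per person and one integer column per scale,
#' validating every score against the declared theoretical ranges. Missing
#' values (empty cells or a designated code) are allowed; a pair's
#' contingency table later uses only persons with both scores present.
#'
#' @param path CSV file path.
#' @param ranges Optional named list/vector giving the theoretical maximum
#'   score of each scale column, e.g. `c(ess = 24, mos = 24)`. Columns not
#'   named are accepted with their observed range.
#' @param id_col Optional name of a person-identifier column; duplicate
#'   identifiers raise an error.
#' @param missing_code Optional numeric code to be read as missing.
#' @return A tibble of scores with the declared `ranges` attached as an
#'   attribute.
#' @export
read_scores <- function(path, ranges = NULL, id_col = NULL,
                        missing_code = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(id_col)) {
    if (!id_col %in% names(d)) abort(sprintf("No column '%s'.", id_col))
    if (anyDuplicated(d[[id_col]])) {
      abort(sprintf("Duplicate person identifiers in '%s': %s", id_col,
                    paste(utils::head(unique(d[[id_col]][duplicated(d[[id_col]])]), 5),
                          collapse = ", ")))
    }
  }
  numeric_cols <- names(d)[vapply(d, is.numeric, logical(1))]
  if (!is.null(ranges)) {
    bad <- setdiff(names(ranges), numeric_cols)
    if (length(bad) > 0) {
      abort(sprintf("Declared range for non-numeric column(s): %s",
                    paste(bad, collapse = ", ")))
    }
  }
  for (col in setdiff(numeric_cols, id_col)) {
    x <- d[[col]]
    if (!is.null(missing_code)) {
      x[x == missing_code] <- NA
      d[[col]] <- x
    }
    ok <- is.na(x) | (x == round(x) & x >= 0)
    if (!all(ok)) {
      abort(sprintf("Column '%s' has non-integer or negative scores in rows: %s",
                    col, paste(utils::head(which(!ok), 5), collapse = ", ")))
    }
    if (!is.null(ranges) && col %in% names(ranges)) {
      mx <- max(ranges[[col]])
      bad <- which(!is.na(x) & x > mx)
      if (length(bad) > 0) {
        abort(sprintf(
          "Column '%s' has scores above the declared maximum %d in rows: %s",
          col, mx, paste(utils::head(bad, 5), collapse = ", ")),
          class = "psq_out_of_range")
      }
    }
  }
  attr(d, "ranges") <- ranges
  d
}

#' Write / read an equating table
#'
#' The table is written as a plain CSV with columns `source_score`,
#' `expected_target`, `equated_target`, `see` and `weight`, plus a JSON
#' summary (scales, weighted SEE mean and its acceptability, number of
#' bootstrap replicates, seed) so every number is replayable. Reading the
#' pair restores the `psq_equating` object.
#'
#' @param x A `psq_equating` tibble.
#' @param path CSV output path.
#' @param summary_path JSON summary path; default replaces the CSV
#'   extension with `.json`.
#' @return `write_equating_table()` returns `x` invisibly;
#'   `read_equating_table()` returns the restored table.
#' @export
write_equating_table <- function(x, path, summary_path = NULL) {
  stopifnot(inherits(x, "psq_equating"))
  summary_path <- summary_path %||% sub("\\.csv$", ".json", path)
  cols <- intersect(c("source_score", "theta", "expected_via",
                      "expected_target", "equated_target", "see", "weight"),
                    names(x))
  readr::write_csv(x[, cols], path)
  summary <- list(
    source = attr(x, "source"), target = attr(x, "target"),
    via = attr(x, "via"),
    weighted_see_mean = attr(x, "weighted_see_mean"),
    see_acceptable = attr(x, "see_acceptable"),
    n_boot = attr(x, "n_boot"), seed = attr(x, "seed"),
    n_failed = attr(x, "n_failed")
  )
  jsonlite::write_json(summary[!vapply(summary, is.null, logical(1))],
                       summary_path, auto_unbox = TRUE, digits = NA)
  invisible(x)
}

#' @rdname write_equating_table
#' @export
read_equating_table <- function(path, summary_path = NULL) {
  summary_path <- summary_path %||% sub("\\.csv$", ".json", path)
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  s <- if (file.exists(summary_path)) jsonlite::read_json(summary_path) else list()
  new_equating(d,
               source = s$source %||% "a", target = s$target %||% "b",
               via = s$via,
               weighted_see_mean = s$weighted_see_mean,
               see_acceptable = s$see_acceptable,
               n_boot = s$n_boot, seed = s$seed, n_failed = s$n_failed)
}

#' Write a fit-test report as flat JSON
#'
#' Serialises a [fit_tests()] report as a flat key-value JSON object
#' (statistics, p-values, misfit count/proportion/interval, bootstrap size,
#' seed and verdict).
#'
#' @param report A `leunbach_fit_report`.
#' @param path Output path.
#' @return The report, invisibly.
#' @export
write_fit_report <- function(report, path) {
  stopifnot(inherits(report, "leunbach_fit_report"))
  out <- list(
    lrt_statistic = report$lrt_statistic, lrt_p = report$lrt_p,
    gamma_observed = report$gamma_observed,
    gamma_expected = report$gamma_expected, gamma_p = report$gamma_p,
    misfit_count = report$misfit_count,
    misfit_proportion = report$misfit_proportion,
    misfit_ci_lower = report$misfit_ci[1],
    misfit_ci_upper = report$misfit_ci[2],
    misfit_p = report$misfit_p,
    n = report$n, n_bootstrap = report$n_bootstrap,
    seed = report$seed, verdict = report$verdict
  )
  jsonlite::write_json(out[!vapply(out, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
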