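#' Run the full QA evaluation on a worksheet file
#'
#' The one-call entry point: read the worksheet, evaluate every record
#' against the supplied (or self-computed) per-type calibration factors,
#' aggregate per-type statistics, bin the deviation histogram, and collect a
#' flag summary. Optionally writes the evaluated worksheet, group statistics
#' and histogram as CSVs.
#'
#' @param worksheet_path Path to a worksheet CSV (see [read_worksheet()]).
#' @param type_factors Optional path to, or tibble of, per-type factors with
#'   `plaque_type` and `mean_factor` columns; `NULL` computes group means
#'   from the worksheet itself.
#' @param constants A [plaque_constants()] object.
#' @param limits A [qa_limits()] object.
#' @param out_dir Optional output directory for
#'   `evaluated_worksheet.csv`, `group_statistics.csv`,
#'   `deviation_histogram.csv` and `flag_summary.csv`.
#' @param bin_width Histogram bin width in percentage points.
#' @return A list of class `plaque_qa_report`: `results` (the evaluated
#'   worksheet), `group_stats`, `histogram`, `flags` (one row per flagged
#'   plaque with the flag kind and magnitude) and `ok` (`TRUE` when no
#'   action-limit or cross-check flag was raised).
#' @export
run_qa <- function(worksheet_path, type_factors = NULL,
                   constants = plaque_constants(), limits = qa_limits(),
                   out_dir = NULL, bin_width = 1) {
  records <- read_worksheet(worksheet_path)
  if (is.character(type_factors)) {
    type_factors <- readr::read_csv(type_factors, show_col_types = FALSE,
                                    progress = FALSE)
  }
  results <- evaluate_worksheet(records, group_mean_factor = type_factors,
                                constants = constants, limits = limits)
  group_stats <- group_statistics(results)
  histogram <- deviation_histogram(results$deviation_pct,
                                   bin_width = bin_width)
  flags <- flag_summary(results)
  ok <- !any(results$flag_action_limit | results$flag_cross_check,
             na.rm = TRUE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_worksheet(results, file.path(out_dir, "evaluated_worksheet.csv"))
    readr::write_csv(group_stats, file.path(out_dir, "group_statistics.csv"))
    readr::write_csv(histogram, file.path(out_dir, "deviation_histogram.csv"))
    readr::write_csv(flags, file.path(out_dir, "flag_summary.csv"))
  }
  structure(
    list(results = results, group_stats = group_stats,
         histogram = histogram, flags = flags, ok = ok),
    class = "plaque_qa_report"
  )
}

flag_summary <- function(results) {
  rows <- list()
  add <- function(idx, kind, magnitude) {
    if (!any(idx)) return()
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      plaque_id = results$plaque_id[idx],
      plaque_type = results$plaque_type[idx],
      flag = kind,
      magnitude_pct = magnitude[idx]
    )
  }
  add(isTRUE_vec(results$flag_action_limit), "ACTION_LIMIT",
      results$deviation_pct)
  add(isTRUE_vec(results$flag_reading_spread), "READING_SPREAD",
      results$spread_pct)
  if ("flag_cross_check" %in% names(results)) {
    add(isTRUE_vec(results$flag_cross_check), "CROSS_CHECK",
        rep(NA_real_, nrow(results)))
  }
  if (length(rows) == 0) {
    return(tibble::tibble(plaque_id = character(), plaque_type = character(),
                          flag = character(), magnitude_pct = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' @export
print.plaque_qa_report <- function(x, ...) {
  cat("<plaque_qa_report>\n")
  cat("  ", nrow(x$results), " plaque(s), ",
      nrow(x$group_stats), " type(s)\n", sep = "")
  if (nrow(x$flags) == 0) {
    cat("  no flags raised\n")
  } else {
    cat("  flags:\n")
    for (i in seq_len(nrow(x$flags))) {
      cat(sprintf("    plaque %s (%s): %s%s\n",
                  x$flags$plaque_id[i], x$flags$plaque_type[i],
                  x$flags$flag[i],
                  if (is.na(x$flags$magnitude_pct[i])) "" else
                    sprintf(" at %+.1f%%", x$flags$magnitude_pct[i])))
    }
  }
  invisible(x)
}

#' Log a dose-calibrator constancy check
#'
#' Before each plaque measurement the calibrator's stability is verified
#' against a long-lived Cs-137 check source. This records the reading, the
#' percent difference from the expected value, and pass/fail at the given
#' tolerance. Informational: a failed constancy check is reported but does
#' not block evaluation.
#'
#' @param reading Measured check-source value.
#' @param expected Expected (decayed reference) value; must be positive.
#' @param tolerance_pct Pass tolerance in percent (default 5).
#' @return A one-row tibble with `reading`, `expected`, `diff_pct`, `pass`.
#' @examples
#' constancy_check(102, 100)
#' @export
constancy_check <- function(reading, expected, tolerance_pct = 5) {
  stopifnot(expected > 0, tolerance_pct > 0)
  diff_pct <- 100 * (reading / expected - 1)
  tibble::tibble(
    reading = reading,
    expected = expected,
    diff_pct = diff_pct,
    pass = abs(diff_pct) <= tolerance_pct
  )
}
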