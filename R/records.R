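#' Default plaque types and seed capacities
#'
#' COMS plaques come in 10-22 mm diameters ("N" marks notched variants that
#' fit around the optic nerve); the Eye Physics EP917 has 17 collimating
#' slots. Fully loaded COMS plaques hold between 5 and 24 seeds depending on
#' diameter; the per-type capacities here span that range and are editable —
#' pass your own table to the readers if your carriers differ.
#'
#' @return A tibble with columns `plaque_type` and `capacity`.
#' @export
plaque_capacities <- function() {
  tibble::tibble(
    plaque_type = c("COMS10", "COMS12", "COMS12N", "COMS14", "COMS14N",
                    "COMS16", "COMS16N", "COMS18", "COMS18N", "COMS20",
                    "COMS20N", "COMS22", "EP917"),
    capacity = c(5L, 8L, 8L, 13L, 13L, 13L, 13L, 21L, 21L, 24L, 24L, 24L, 17L)
  )
}

#' Read a plaque calibration worksheet
#'
#' Reads the CSV worksheet schema: one row per plaque with the assay
#' certificate (seed count, assay date, total air kerma strength in U),
#' the measurement session (date plus either four angle readings at
#' 0/90/180/270 degrees or a single pre-averaged activity, mCi), and
#' optionally the plan-record counterparts (`plan_strength_u`, `plan_date`).
#'
#' Column names (configurable via `schema`): `plaque_id`, `plaque_type`,
#' `n_seeds`, `assay_date`, `assay_strength_u`, `measurement_date`, and either
#' `reading_0`, `reading_90`, `reading_180`, `reading_270` or `activity_mci`.
#'
#' Row-level problems (unknown plaque type, seed count above capacity,
#' measurement date far from the assay date) are reported as warnings naming
#' the row and column; only an empty file or a missing required column is an
#' error.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(plaque_id = "ID")`.
#' @param month_first Interpret slash dates month-first (worksheet style).
#' @param capacities Capacity table as from [plaque_capacities()].
#' @param date_window_days Warn when |measurement - assay| exceeds this many
#'   days (default 365).
#' @return A tibble of validated records, one row per plaque, with a
#'   `provenance` column recording whether readings were raw angles or a
#'   pre-averaged activity and a `row` column preserving file row numbers.
#' @export
read_worksheet <- function(path, schema = NULL, month_first = TRUE,
                           capacities = plaque_capacities(),
                           date_window_days = 365) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) stop("no records in ", path, call. = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (schema[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == schema[[canon]]] <- canon
      }
    }
  }
  required <- c("plaque_id", "plaque_type", "n_seeds", "assay_date",
                "assay_strength_u", "measurement_date")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  reading_cols <- c("reading_0", "reading_90", "reading_180", "reading_270")
  has_readings <- all(reading_cols %in% names(raw))
  has_activity <- "activity_mci" %in% names(raw)
  if (!has_readings && !has_activity) {
    stop("need either the four reading_* columns or `activity_mci`",
         call. = FALSE)
  }

  rec <- tibble::tibble(
    row = seq_len(nrow(raw)),
    plaque_id = as.character(raw$plaque_id),
    plaque_type = as.character(raw$plaque_type),
    n_seeds = as.integer(raw$n_seeds),
    assay_date = parse_worksheet_date(raw$assay_date, month_first),
    assay_strength_u = as.numeric(raw$assay_strength_u),
    measurement_date = parse_worksheet_date(raw$measurement_date, month_first)
  )
  if (has_readings) {
    for (col in reading_cols) rec[[col]] <- as.numeric(raw[[col]])
    rec$activity_mci <- if (has_activity) as.numeric(raw$activity_mci) else NA_real_
    rec$provenance <- ifelse(
      rowSums(is.na(as.matrix(rec[reading_cols]))) == 0, "angles",
      ifelse(!is.na(rec$activity_mci), "pre-averaged", NA_character_))
  } else {
    rec$activity_mci <- as.numeric(raw$activity_mci)
    rec$provenance <- ifelse(!is.na(rec$activity_mci), "pre-averaged",
                             NA_character_)
  }
  if ("plan_strength_u" %in% names(raw)) {
    rec$plan_strength_u <- as.numeric(raw$plan_strength_u)
  }
  if ("plan_date" %in% names(raw)) {
    rec$plan_date <- parse_worksheet_date(raw$plan_date, month_first)
  }

  validate_records(rec, capacities, date_window_days)
  rec
}

validate_records <- function(rec, capacities, date_window_days) {
  diag <- function(row, col, msg) {
    warning(sprintf("row %d, column %s: %s", row, col, msg), call. = FALSE)
  }
  cap <- stats::setNames(capacities$capacity, capacities$plaque_type)
  for (i in seq_len(nrow(rec))) {
    if (is.na(rec$provenance[i])) {
      diag(rec$row[i], "readings",
           "neither four angle readings nor an averaged activity present")
    }
    if (!rec$plaque_type[i] %in% names(cap)) {
      diag(rec$row[i], "plaque_type",
           paste0("unknown plaque type '", rec$plaque_type[i], "'"))
    } else if (!is.na(rec$n_seeds[i]) &&
               rec$n_seeds[i] > cap[[rec$plaque_type[i]]]) {
      diag(rec$row[i], "n_seeds",
           sprintf("%d seeds exceeds %s capacity of %d",
                   rec$n_seeds[i], rec$plaque_type[i],
                   cap[[rec$plaque_type[i]]]))
    }
    if (!is.na(rec$n_seeds[i]) && rec$n_seeds[i] < 1) {
      diag(rec$row[i], "n_seeds", "seed count must be at least 1")
    }
    if (!is.na(rec$assay_strength_u[i]) && rec$assay_strength_u[i] <= 0) {
      diag(rec$row[i], "assay_strength_u", "assay strength must be positive")
    }
    dt <- abs(as.integer(rec$measurement_date[i] - rec$assay_date[i]))
    if (!is.na(dt) && dt > date_window_days) {
      diag(rec$row[i], "measurement_date",
           sprintf("measurement %d days from assay (window %d)",
                   dt, date_window_days))
    }
  }
  invisible(rec)
}

#' Write an evaluated worksheet
#'
#' Renders a calibration-result table in the printed worksheet layout: assay
#' data, measured data, the decayed strength and calibration factor, the
#' deviation from the group mean, and a `flagged` marker column for rows
#' whose deviation exceeds the action limit (the printed worksheet highlights
#' these in red). Strengths are rounded to 2 dp, factors to 3 dp and
#' deviations to 1 dp here — and only here; all upstream math is full
#' precision.
#'
#' @param results An evaluated worksheet from [evaluate_worksheet()].
#' @param path Output CSV path.
#' @return The rendered tibble, invisibly.
#' @export
write_worksheet <- function(results, path) {
  needed <- c("plaque_id", "n_seeds", "assay_date", "assay_strength_u",
              "measurement_date", "mean_activity_mci", "measured_strength_u",
              "decayed_strength_u", "cal_factor")
  missing_cols <- setdiff(needed, names(results))
  if (length(missing_cols) > 0) {
    stop("`results` lacks column(s): ", paste(missing_cols, collapse = ", "),
         "; evaluate the worksheet first", call. = FALSE)
  }
  out <- tibble::tibble(
    plaque_id = results$plaque_id,
    n_seeds = results$n_seeds,
    assay_date = format(results$assay_date, "%m/%d/%Y"),
    assay_strength_u = sprintf("%.2f", results$assay_strength_u),
    measurement_date = format(results$measurement_date, "%m/%d/%Y"),
    activity_mci = sprintf("%.2f", results$mean_activity_mci),
    measured_strength_u = sprintf("%.2f", results$measured_strength_u),
    decayed_strength_u = sprintf("%.2f", results$decayed_strength_u),
    cal_factor = sprintf("%.3f", results$cal_factor)
  )
  if ("deviation_pct" %in% names(results)) {
    out$deviation_pct <- ifelse(is.na(results$deviation_pct), "",
                                sprintf("%.1f%%", results$deviation_pct))
    out$flagged <- ifelse(isTRUE_vec(results$flag_action_limit), "*", "")
  }
  readr::write_csv(out, path)
  invisible(out)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Bundled example data
#'
#' Small plain-text datasets shipped with the package: the first ten EP917
#' plaques of the calibration worksheet (`"worksheet"`), the per-position
#' single-seed activities for three EP917 plaques (`"seed_contribution"`),
#' and the per-type COMS calibration-factor summary (`"coms_factors"`).
#'
#' @param which One of `"worksheet"`, `"seed_contribution"`, `"coms_factors"`.
#' @return A tibble.
#' @examples
#' example_data("worksheet")
#' @export
example_data <- function(which = c("worksheet", "seed_contribution",
                                   "coms_factors")) {
  which <- match.arg(which)
  file <- switch(which,
    worksheet = "ep917_worksheet.csv",
    seed_contribution = "ep917_seed_contribution.csv",
    coms_factors = "coms_type_factors.csv"
  )
  path <- system.file("extdata", file, package = "plaqueqa", mustWork = TRUE)
  if (which == "worksheet") {
    read_worksheet(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}
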