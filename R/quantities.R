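#' Physical constants for I-125 plaque verification
#'
#' Bundles the nuclide half-life and the conversion between apparent activity
#' read by a dose calibrator (mCi) and air kerma strength (U, 1 U = 1
#' uGy m^2 / h). The defaults are the I-125 values used throughout the
#' worksheet calculations: a 59.4 day half-life and 1.270 U per mCi
#' (equivalently 1 U = 0.787 mCi).
#'
#' @param half_life_days Nuclide half-life in days. Must be positive.
#' @param u_per_mci Conversion factor from apparent activity (mCi) to air
#'   kerma strength (U). Use `1 / mci_per_u` to adopt the inverse convention.
#' @param mci_per_u Stated inverse conversion (mCi per U). Checked for
#'   consistency with `u_per_mci` to within 0.3 percent.
#'
#' @return A list of class `plaque_constants`.
#' @examples
#' plaque_constants()
#' plaque_constants(u_per_mci = 1 / 0.787)
#' @export
plaque_constants <- function(half_life_days = 59.4,
                             u_per_mci = 1.270,
                             mci_per_u = 0.787) {
  stopifnot(
    is.numeric(half_life_days), length(half_life_days) == 1L, half_life_days > 0,
    is.numeric(u_per_mci), length(u_per_mci) == 1L, u_per_mci > 0,
    is.numeric(mci_per_u), length(mci_per_u) == 1L, mci_per_u > 0
  )
  if (abs(u_per_mci * mci_per_u - 1) > 0.003) {
    stop("`u_per_mci` and `mci_per_u` are inconsistent: their product ",
         format(u_per_mci * mci_per_u, digits = 6),
         " differs from 1 by more than 0.3%", call. = FALSE)
  }
  structure(
    list(half_life_days = half_life_days,
         u_per_mci = u_per_mci,
         mci_per_u = mci_per_u),
    class = "plaque_constants"
  )
}

#' @export
print.plaque_constants <- function(x, ...) {
  cat("<plaque_constants>\n")
  cat("  half-life: ", x$half_life_days, " days\n", sep = "")
  cat("  1 mCi = ", x$u_per_mci, " U  (1 U = ", x$mci_per_u, " mCi)\n", sep = "")
  invisible(x)
}

#' Convert apparent activity to air kerma strength
#'
#' Multiplies a dose-calibrator activity reading (mCi) by the U-per-mCi
#' conversion factor. Vectorised; full precision is kept — round only when
#' printing worksheet values.
#'
#' @param activity_mci Apparent activity in mCi; must be non-negative.
#' @param constants A [plaque_constants()] object.
#' @param label Optional record label used in error messages.
#' @return Air kerma strength in U.
#' @examples
#' activity_to_strength(20.30) # 25.78 U at 2 dp
#' @export
activity_to_strength <- function(activity_mci, constants = plaque_constants(),
                                 label = NULL) {
  check_constants(constants)
  bad <- which(is.finite(activity_mci) & activity_mci < 0)
  if (length(bad) > 0) {
    stop("negative activity for ",
         if (is.null(label)) paste("element", bad[1]) else label[bad[1]],
         ": ", activity_mci[bad[1]], " mCi", call. = FALSE)
  }
  activity_mci * constants$u_per_mci
}

#' Convert air kerma strength to apparent activity
#'
#' @inheritParams activity_to_strength
#' @param strength_u Air kerma strength in U; must be non-negative.
#' @return Apparent activity in mCi.
#' @export
strength_to_activity <- function(strength_u, constants = plaque_constants()) {
  check_constants(constants)
  stopifnot(all(strength_u >= 0, na.rm = TRUE))
  strength_u / constants$u_per_mci
}

#' Signed whole days between two calendar dates
#'
#' Computes `to_date - from_date` in days; negative when the measurement
#' precedes the assay, as happens when a plaque is measured before its
#' certificate's assay date.
#'
#' @param from_date,to_date `Date` vectors, or strings parseable by
#'   [parse_worksheet_date()].
#' @param month_first Passed to [parse_worksheet_date()] for string input.
#' @return Integer vector of signed day counts.
#' @examples
#' elapsed_days("9/16/2011", "10/23/2011") # 37
#' elapsed_days("4/2/2012", "3/30/2012")   # -3
#' @export
elapsed_days <- function(from_date, to_date, month_first = TRUE) {
  from_date <- parse_worksheet_date(from_date, month_first = month_first)
  to_date <- parse_worksheet_date(to_date, month_first = month_first)
  as.integer(to_date - from_date)
}

#' Parse worksheet dates
#'
#' Accepts `Date` input unchanged, ISO-8601 (`2011-09-16`) and the worksheet's
#' month/day/year form (`9/16/2011`). Slash-separated dates are read
#' month-first by default; set `month_first = FALSE` for day/month/year.
#'
#' @param x A `Date` vector or character vector of dates.
#' @param month_first Logical; interpret `a/b/yyyy` as month/day (default)
#'   rather than day/month.
#' @return A `Date` vector.
#' @export
parse_worksheet_date <- function(x, month_first = TRUE) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  slash <- grepl("/", x, fixed = TRUE)
  fmt <- if (month_first) "%m/%d/%Y" else "%d/%m/%Y"
  out[slash] <- as.Date(x[slash], format = fmt)
  out[!slash] <- as.Date(x[!slash], format = "%Y-%m-%d")
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("unparseable date(s): ", paste(x[bad], collapse = ", "), call. = FALSE)
  }
  out
}

#' Decay-correct an air kerma strength between two dates
#'
#' Applies exponential radioactive decay `strength * 2^(-elapsed / half_life)`
#' where `elapsed` is the signed whole-day interval from `from_date` to
#' `to_date`. A negative interval (measurement before assay) grows the
#' strength; a zero interval returns the input exactly.
#'
#' @param strength_u Air kerma strength in U at `from_date`; non-negative.
#' @param from_date,to_date Dates (see [parse_worksheet_date()]).
#' @param constants A [plaque_constants()] object.
#' @param month_first Passed to the date parser.
#' @return Strength in U at `to_date`.
#' @examples
#' decay_correct(115.60, "9/16/2011", "10/23/2011") # 75.07 U at 2 dp
#' @export
decay_correct <- function(strength_u, from_date, to_date,
                          constants = plaque_constants(), month_first = TRUE) {
  check_constants(constants)
  if (any(strength_u < 0, na.rm = TRUE)) {
    stop("negative strength cannot be decay-corrected", call. = FALSE)
  }
  dt <- elapsed_days(from_date, to_date, month_first = month_first)
  strength_u * 2^(-dt / constants$half_life_days)
}

check_constants <- function(constants) {
  if (!inherits(constants, "plaque_constants")) {
    stop("`constants` must be created by plaque_constants()", call. = FALSE)
  }
  invisible(constants)
}
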