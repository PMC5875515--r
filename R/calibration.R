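#' QA tolerance limits
#'
#' The three thresholds used by the verification worksheet: the 4% limit on
#' the spread of the four angle readings (above it the plaque should be
#' repositioned and remeasured), the 5% action limit on a calibration
#' factor's deviation from its plaque-type mean (AAPM low-energy source
#' calibration guidance for batch measurements of preloaded assemblies), and
#' the 5% limit on the plan-vs-assay cross-checks.
#'
#' @param reading_spread_pct Max allowed percent spread of the four readings.
#' @param action_limit_pct Action limit on |deviation from group mean|.
#' @param cross_check_pct Limit on plan/assay disagreement.
#' @return A list of class `qa_limits`.
#' @export
qa_limits <- function(reading_spread_pct = 4,
                      action_limit_pct = 5,
                      cross_check_pct = 5) {
  stopifnot(reading_spread_pct > 0, action_limit_pct > 0, cross_check_pct > 0)
  structure(
    list(reading_spread_pct = reading_spread_pct,
         action_limit_pct = action_limit_pct,
         cross_check_pct = cross_check_pct),
    class = "qa_limits"
  )
}

#' Average the four angle readings and check their spread
#'
#' The plaque is measured with the calibrator's sample holder rotated to 0,
#' 90, 180 and 270 degrees; the mean of the four activities is the plaque
#' activity, and their spread, `100 * (max - min) / mean`, signals poor
#' centering when it exceeds the reading-spread limit (the protocol is then
#' to reposition and repeat; the software can only flag). The metric can be
#' switched to `(max - min) / min`.
#'
#' @param reading_0,reading_90,reading_180,reading_270 Activity readings in
#'   mCi, each non-negative; vectors are evaluated element-wise.
#' @param limits A [qa_limits()] object.
#' @param spread_metric Denominator for the spread: the mean of the four
#'   readings (default) or their minimum.
#' @return A tibble with `mean_activity_mci`, `spread_pct`, `spread_ok`.
#' @examples
#' average_readings(20.0, 20.4, 20.2, 20.6)
#' @export
average_readings <- function(reading_0, reading_90, reading_180, reading_270,
                             limits = qa_limits(),
                             spread_metric = c("mean", "min")) {
  spread_metric <- match.arg(spread_metric)
  r <- cbind(reading_0, reading_90, reading_180, reading_270)
  if (any(r < 0, na.rm = TRUE)) {
    stop("angle readings must be non-negative", call. = FALSE)
  }
  m <- rowMeans(r)
  if (any(!is.na(m) & m == 0)) {
    stop("all four readings are zero: spread undefined", call. = FALSE)
  }
  rng <- apply(r, 1, max) - apply(r, 1, min)
  denom <- if (spread_metric == "mean") m else apply(r, 1, min)
  spread <- 100 * rng / denom
  tibble::tibble(
    mean_activity_mci = m,
    spread_pct = spread,
    spread_ok = spread <= limits$reading_spread_pct
  )
}

#' Plaque calibration factor
#'
#' The method's central statistic: the measured air kerma strength of the
#' assembled plaque divided by its decay-corrected assay strength. The
#' factor is well below 1 because the gold plaque body shields laterally
#' directed radiation from the calibrator's well; it is stable within a
#' plaque type, which is what makes it usable for verification.
#'
#' @param measured_strength_u Measured plaque strength in U.
#' @param decayed_strength_u Assay strength decayed to the measurement date, U.
#' @return Dimensionless calibration factor (full precision; print at 3 dp).
#' @examples
#' calibration_factor(25.78, 75.07) # ~0.343
#' @export
calibration_factor <- function(measured_strength_u, decayed_strength_u) {
  if (any(decayed_strength_u <= 0, na.rm = TRUE)) {
    stop("decayed assay strength must be positive", call. = FALSE)
  }
  if (any(measured_strength_u <= 0, na.rm = TRUE)) {
    stop("measured strength must be positive", call. = FALSE)
  }
  measured_strength_u / decayed_strength_u
}

#' Percent deviation of a calibration factor from its group mean
#'
#' `100 * (cal_factor / group_mean - 1)`. Deviations beyond the action limit
#' mark plaques for investigation.
#'
#' @param cal_factor Calibration factor(s).
#' @param group_mean_factor The plaque-type mean factor; must be positive.
#' @return Percent deviation (full precision; print at 1 dp).
#' @examples
#' deviation_from_mean(0.374, 0.353) # ~ +5.9
#' @export
deviation_from_mean <- function(cal_factor, group_mean_factor) {
  if (any(group_mean_factor <= 0, na.rm = TRUE)) {
    stop("group mean factor must be positive", call. = FALSE)
  }
  100 * (cal_factor / group_mean_factor - 1)
}

#' Evaluate a worksheet of plaque records
#'
#' Runs the full verification chain on each record: average the four angle
#' readings (or take the stored pre-averaged activity), convert the mean
#' activity to air kerma strength, decay the assay certificate strength to
#' the measurement date, form the calibration factor, and — when a group
#' mean is available — the percent deviation and action-limit flag. When the
#' record carries plan data, the plan-vs-assay cross-checks are evaluated
#' too.
#'
#' @param records A records tibble as from [read_worksheet()] or
#'   [simulate_records()].
#' @param group_mean_factor Either a single number applied to all records, a
#'   tibble with `plaque_type` and `mean_factor` columns (as from
#'   [group_statistics()]), or `NULL` to compute each type's mean from the
#'   records themselves. Group-mean provenance is deliberately explicit:
#'   pass the historical per-type factors when checking new plaques against
#'   an established baseline.
#' @param constants A [plaque_constants()] object.
#' @param limits A [qa_limits()] object.
#' @return A tibble of class `plaque_calibration`: the input records plus
#'   `mean_activity_mci`, `spread_pct`, `measured_strength_u`,
#'   `decayed_strength_u`, `cal_factor`, `group_mean_factor`,
#'   `deviation_pct`, and logical `flag_reading_spread`, `flag_action_limit`,
#'   `flag_cross_check` columns.
#' @examples
#' ws <- example_data("worksheet")
#' evaluate_worksheet(ws, group_mean_factor = 0.353)
#' @export
evaluate_worksheet <- function(records,
                               group_mean_factor = NULL,
                               constants = plaque_constants(),
                               limits = qa_limits()) {
  check_constants(constants)
  stopifnot(inherits(limits, "qa_limits"), is.data.frame(records),
            nrow(records) > 0)

  res <- tibble::as_tibble(records)
  reading_cols <- c("reading_0", "reading_90", "reading_180", "reading_270")
  has_angles <- all(reading_cols %in% names(res))

  if (has_angles) {
    use_angles <- rowSums(is.na(as.matrix(res[reading_cols]))) == 0
  } else {
    use_angles <- rep(FALSE, nrow(res))
  }
  mean_act <- spread <- rep(NA_real_, nrow(res))
  if (any(use_angles)) {
    avg <- average_readings(res$reading_0[use_angles],
                            res$reading_90[use_angles],
                            res$reading_180[use_angles],
                            res$reading_270[use_angles],
                            limits = limits)
    mean_act[use_angles] <- avg$mean_activity_mci
    spread[use_angles] <- avg$spread_pct
  }
  if ("activity_mci" %in% names(res)) {
    pre <- !use_angles & !is.na(res$activity_mci)
    mean_act[pre] <- res$activity_mci[pre]
  }
  if (any(is.na(mean_act))) {
    stop("record(s) without readings or activity: ",
         paste(utils::head(res$plaque_id[is.na(mean_act)], 3), collapse = ", "),
         call. = FALSE)
  }

  res$mean_activity_mci <- mean_act
  res$spread_pct <- spread
  res$flag_reading_spread <- !is.na(spread) &
    spread > limits$reading_spread_pct
  res$measured_strength_u <- activity_to_strength(mean_act, constants,
                                                  label = res$plaque_id)
  res$decayed_strength_u <- decay_correct(res$assay_strength_u,
                                          res$assay_date,
                                          res$measurement_date, constants)
  res$cal_factor <- calibration_factor(res$measured_strength_u,
                                       res$decayed_strength_u)

  res$group_mean_factor <- resolve_group_mean(res, group_mean_factor)
  res$deviation_pct <- ifelse(
    is.na(res$group_mean_factor), NA_real_,
    deviation_from_mean(res$cal_factor, res$group_mean_factor))
  res$flag_action_limit <- !is.na(res$deviation_pct) &
    abs(res$deviation_pct) > limits$action_limit_pct

  res$flag_cross_check <- cross_check_flags(res, constants, limits)

  class(res) <- c("plaque_calibration", class(res))
  attr(res, "constants") <- constants
  attr(res, "limits") <- limits
  res
}

resolve_group_mean <- function(res, group_mean_factor) {
  if (is.null(group_mean_factor)) {
    stats_tbl <- dplyr::summarise(
      dplyr::group_by(res, .data$plaque_type),
      mean_factor = mean(.data$cal_factor), .groups = "drop")
    group_mean_factor <- stats_tbl
  }
  if (is.data.frame(group_mean_factor)) {
    stopifnot(all(c("plaque_type", "mean_factor") %in%
                    names(group_mean_factor)))
    idx <- match(res$plaque_type, group_mean_factor$plaque_type)
    return(group_mean_factor$mean_factor[idx])
  }
  stopifnot(is.numeric(group_mean_factor), all(group_mean_factor > 0))
  rep_len(group_mean_factor, nrow(res))
}

cross_check_flags <- function(res, constants, limits) {
  flag <- rep(FALSE, nrow(res))
  if (!"plan_strength_u" %in% names(res)) return(flag)
  have_plan <- !is.na(res$plan_strength_u)
  if (!any(have_plan)) return(flag)
  plan_date <- if ("plan_date" %in% names(res)) res$plan_date else res$assay_date
  plan_date <- dplyr::coalesce(plan_date, res$assay_date)
  # align plan strength to the measurement date before comparing
  plan_dec <- decay_correct(res$plan_strength_u[have_plan],
                            plan_date[have_plan],
                            res$measurement_date[have_plan], constants)
  strength_diff <- 100 * abs(plan_dec / res$decayed_strength_u[have_plan] - 1)
  factor_plan <- res$measured_strength_u[have_plan] / plan_dec
  factor_diff <- 100 * abs(factor_plan / res$cal_factor[have_plan] - 1)
  flag[have_plan] <- strength_diff > limits$cross_check_pct |
    factor_diff > limits$cross_check_pct
  flag
}

#' Cross-check plan against assay seed data
#'
#' Compares the planned total strength (decayed to the measurement date)
#' with the decayed assay strength, and the plan-based with the assay-based
#' calibration factor; either disagreeing by more than the cross-check limit
#' raises a flag. Catches unit confusion (a 27% shift, from 1/0.787) and
#' order-fulfilment mismatches. Records without plan data are skipped with a
#' message.
#'
#' @param results An evaluated worksheet from [evaluate_worksheet()].
#' @param constants,limits As in [evaluate_worksheet()].
#' @return A tibble with `plaque_id`, percent differences and `flag_cross_check`.
#' @export
cross_check <- function(results, constants = plaque_constants(),
                        limits = qa_limits()) {
  stopifnot(is.data.frame(results))
  if (!"plan_strength_u" %in% names(results) ||
      all(is.na(results$plan_strength_u))) {
    message("no plan data present; cross-check skipped")
    return(tibble::tibble(plaque_id = character(),
                          strength_diff_pct = numeric(),
                          factor_diff_pct = numeric(),
                          flag_cross_check = logical()))
  }
  have <- !is.na(results$plan_strength_u)
  plan_date <- if ("plan_date" %in% names(results)) {
    dplyr::coalesce(results$plan_date, results$assay_date)
  } else results$assay_date
  plan_dec <- decay_correct(results$plan_strength_u[have], plan_date[have],
                            results$measurement_date[have], constants)
  strength_diff <- 100 * abs(plan_dec / results$decayed_strength_u[have] - 1)
  factor_plan <- results$measured_strength_u[have] / plan_dec
  factor_diff <- 100 * abs(factor_plan / results$cal_factor[have] - 1)
  tibble::tibble(
    plaque_id = results$plaque_id[have],
    strength_diff_pct = strength_diff,
    factor_diff_pct = factor_diff,
    flag_cross_check = strength_diff > limits$cross_check_pct |
      factor_diff > limits$cross_check_pct
  )
}

#' @export
print.plaque_calibration <- function(x, ...) {
  limits <- attr(x, "limits")
  cat("<plaque_calibration> ", nrow(x), " plaque(s)\n", sep = "")
  NextMethod()
  n_flag <- sum(x$flag_action_limit, na.rm = TRUE)
  if (!is.null(limits)) {
    cat(n_flag, " plaque(s) beyond the ", limits$action_limit_pct,
        "% action limit\n", sep = "")
  }
  invisible(x)
}

#' Tidy an evaluated worksheet
#'
#' One row per plaque with the quantities a reviewer reads off the
#' worksheet: strengths, calibration factor, deviation and flags.
#'
#' @param x A `plaque_calibration` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy plaque_calibration
#' @export
tidy.plaque_calibration <- function(x, ...) {
  cols <- intersect(
    c("plaque_id", "plaque_type", "n_seeds", "mean_activity_mci",
      "spread_pct", "measured_strength_u", "decayed_strength_u",
      "cal_factor", "group_mean_factor", "deviation_pct",
      "flag_reading_spread", "flag_action_limit", "flag_cross_check"),
    names(x))
  tibble::as_tibble(x)[cols]
}

#' One-row summary of an evaluated worksheet
#'
#' @param x A `plaque_calibration` object.
#' @param ... Unused.
#' @return A tibble with counts of records and flags and the factor spread.
#' @method glance plaque_calibration
#' @export
glance.plaque_calibration <- function(x, ...) {
  tibble::tibble(
    n_plaques = nrow(x),
    n_types = dplyr::n_distinct(x$plaque_type),
    mean_cal_factor = mean(x$cal_factor),
    cv_pct = 100 * stats::sd(x$cal_factor) / mean(x$cal_factor),
    n_flag_action = sum(x$flag_action_limit, na.rm = TRUE),
    n_flag_spread = sum(x$flag_reading_spread, na.rm = TRUE),
    n_flag_cross = sum(x$flag_cross_check, na.rm = TRUE)
  )
}
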