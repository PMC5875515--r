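#' Per-position contribution fractions from single-seed placements
#'
#' First of the two ways to measure how much each slot of a loaded plaque
#' contributes to its total activity: place one seed in each position in
#' turn and record the calibrator activity. The contribution of position i
#' is `activity_i / sum(activities)`, so the fractions sum to exactly 1.
#'
#' @param activities Per-position activities in mCi, all positive.
#' @return A tibble with `position`, `activity_mci`, `fraction` and
#'   `pct_of_total`.
#' @examples
#' contributions_from_placements(c(1.0, 1.1, 0.9))
#' @export
contributions_from_placements <- function(activities) {
  if (any(!is.finite(activities)) || any(activities <= 0)) {
    stop("placement activities must all be positive", call. = FALSE)
  }
  frac <- activities / sum(activities)
  tibble::tibble(
    position = seq_along(activities),
    activity_mci = activities,
    fraction = frac,
    pct_of_total = 100 * frac
  )
}

#' Per-position contribution fractions from one-at-a-time removals
#'
#' Second method: measure the fully loaded plaque, then remove one seed at a
#' time and measure the remainder. Position i's contribution is
#' `(full_total - total_without_i) / full_total`. Because each difference
#' carries two measurements' noise, the fractions need not sum to 1;
#' optional renormalisation to unit sum is recorded in the output.
#'
#' @param full_total Activity of the fully loaded plaque, mCi.
#' @param totals_with_one_removed Activities with each seed removed in turn,
#'   mCi; each must be strictly below `full_total` (a removed seed that
#'   changes nothing signals a measurement error).
#' @param renormalize If `TRUE`, scale fractions to sum to 1.
#' @return A tibble with `position`, `fraction`, `pct_of_total` and a
#'   `renormalized` flag column.
#' @export
contributions_from_removals <- function(full_total, totals_with_one_removed,
                                        renormalize = FALSE) {
  stopifnot(is.numeric(full_total), length(full_total) == 1L, full_total > 0)
  if (any(totals_with_one_removed >= full_total)) {
    bad <- which(totals_with_one_removed >= full_total)[1]
    stop("removed-seed total at position ", bad,
         " is not below the full total: measurement error", call. = FALSE)
  }
  if (any(totals_with_one_removed < 0)) {
    stop("removed-seed totals must be non-negative", call. = FALSE)
  }
  frac <- (full_total - totals_with_one_removed) / full_total
  if (renormalize) frac <- frac / sum(frac)
  tibble::tibble(
    position = seq_along(totals_with_one_removed),
    fraction = frac,
    pct_of_total = 100 * frac,
    renormalized = renormalize
  )
}

#' Summarise seed-position uniformity across plaques
#'
#' Takes per-position contribution percentages from several plaques of the
#' same model, averages them position by position, and summarises the
#' per-position averages by their grand mean and standard deviation. For the
#' 17-slot EP917 the per-position averages cluster tightly around 1/17
#' (about 5.9%), which is what justifies applying one calibration factor to
#' partially loaded plaques.
#'
#' @param contribution_tables A list of per-plaque tibbles as returned by
#'   [contributions_from_placements()] or [contributions_from_removals()];
#'   all must share the same position count.
#' @return A list of class `seed_uniformity` with `per_position` (tibble of
#'   per-position mean percentages and their deviation from the grand mean)
#'   and scalars `grand_mean_pct`, `sd_pct`, `n_plaques`, `n_positions`.
#' @examples
#' tabs <- lapply(1:3, function(i) contributions_from_placements(runif(17, 0.7, 1.3)))
#' uniformity_summary(tabs)
#' @export
uniformity_summary <- function(contribution_tables) {
  stopifnot(is.list(contribution_tables), length(contribution_tables) > 0)
  n_pos <- unname(vapply(contribution_tables, nrow, integer(1)))
  if (length(unique(n_pos)) != 1L) {
    stop("plaques have differing position counts: ",
         paste(unique(n_pos), collapse = ", "), call. = FALSE)
  }
  pct <- vapply(contribution_tables, function(tb) tb$pct_of_total,
                numeric(n_pos[1]))
  per_position_mean <- rowMeans(pct)
  grand_mean <- mean(per_position_mean)
  out <- list(
    per_position = tibble::tibble(
      position = seq_len(n_pos[1]),
      mean_pct = per_position_mean,
      deviation_pct = per_position_mean - grand_mean
    ),
    grand_mean_pct = grand_mean,
    sd_pct = stats::sd(per_position_mean),
    n_plaques = length(contribution_tables),
    n_positions = n_pos[1]
  )
  class(out) <- "seed_uniformity"
  out
}

#' @export
print.seed_uniformity <- function(x, ...) {
  cat("<seed_uniformity> ", x$n_plaques, " plaque(s), ",
      x$n_positions, " positions\n", sep = "")
  cat("  mean contribution ", sprintf("%.1f%%", x$grand_mean_pct),
      " (1/n = ", sprintf("%.1f%%", 100 / x$n_positions), "), sd ",
      sprintf("%.1f%%", x$sd_pct), "\n", sep = "")
  invisible(x)
}

#' @method tidy seed_uniformity
#' @export
tidy.seed_uniformity <- function(x, ...) x$per_position

#' @method glance seed_uniformity
#' @export
glance.seed_uniformity <- function(x, ...) {
  tibble::tibble(
    n_plaques = x$n_plaques,
    n_positions = x$n_positions,
    grand_mean_pct = x$grand_mean_pct,
    sd_pct = x$sd_pct
  )
}

#' Seed-contribution analysis of a wide activity table
#'
#' Convenience wrapper for placement-method data laid out one row per
#' position with one activity column per plaque (the layout of the bundled
#' `example_data("seed_contribution")`).
#'
#' @param activity_table Data frame with a `position` column and one or more
#'   activity columns (mCi).
#' @return A `seed_uniformity` object; the per-plaque fraction tables are
#'   attached as attribute `"tables"`.
#' @examples
#' seed_contribution_analysis(example_data("seed_contribution"))
#' @export
seed_contribution_analysis <- function(activity_table) {
  stopifnot(is.data.frame(activity_table), "position" %in% names(activity_table))
  act_cols <- setdiff(names(activity_table), "position")
  if (length(act_cols) == 0) stop("no activity columns found", call. = FALSE)
  tables <- lapply(act_cols, function(cl) {
    contributions_from_placements(activity_table[[cl]])
  })
  names(tables) <- act_cols
  out <- uniformity_summary(tables)
  attr(out, "tables") <- tables
  out
}
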