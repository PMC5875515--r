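#' Plot the deviation distribution of an evaluated worksheet
#'
#' Histogram of each plaque's percent deviation from its type's mean
#' calibration factor, with the symmetric action limit drawn as dashed
#' lines. Plaques in the tails beyond the limit are the ones the worksheet
#' flags for investigation.
#'
#' @param object A `plaque_calibration` object from [evaluate_worksheet()].
#' @param bin_width Bin width in percentage points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plaque_calibration
#' @export
autoplot.plaque_calibration <- function(object, bin_width = 1, ...) {
  limits <- attr(object, "limits")
  action <- if (is.null(limits)) 5 else limits$action_limit_pct
  h <- deviation_histogram(object$deviation_pct, bin_width = bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = bin_width, fill = "grey35") +
    ggplot2::geom_vline(xintercept = c(-action, action),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "Deviation from mean calibration factor (%)",
      y = "Number of plaques"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-type calibration factors
#'
#' Mean calibration factor per plaque type with +/- one standard deviation
#' error bars, the at-a-glance view of how tightly each type's factor is
#' determined.
#'
#' @param object A `plaque_group_stats` tibble from [group_statistics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plaque_group_stats
#' @export
autoplot.plaque_group_stats <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$plaque_type,
                                       y = .data$mean_factor)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_factor - .data$sd_factor,
                   ymax = .data$mean_factor + .data$sd_factor),
      width = 0.2, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "Plaque calibration factor") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-position seed contributions
#'
#' Per-position mean contribution percentages against the uniform 1/n
#' reference line.
#'
#' @param object A `seed_uniformity` object from [uniformity_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot seed_uniformity
#' @export
autoplot.seed_uniformity <- function(object, ...) {
  ggplot2::ggplot(object$per_position,
                  ggplot2::aes(x = .data$position, y = .data$mean_pct)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 100 / object$n_positions,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "Seed position", y = "Mean % of total activity") +
    ggplot2::theme_minimal()
}
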