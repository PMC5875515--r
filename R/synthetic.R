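#' Configuration for the synthetic record simulator
#'
#' Defines the distribution the simulator draws plaque records from. The
#' per-type true calibration factors and CVs default to the study values:
#' EP917 0.353 with CV 3.29%, and the eleven COMS types with their published
#' per-type means and CVs. Angle noise is independent multiplicative
#' lognormal per reading; the default 1% scale makes the four-reading spread
#' typically around 2-2.5%, comfortably under the 4% repositioning limit,
#' matching a carefully centered plaque.
#'
#' @param type_factors Tibble with `plaque_type`, `mean_factor`, `cv_pct`
#'   giving each type's true-factor distribution.
#' @param reading_noise_sd Lognormal sigma of the per-reading multiplicative
#'   noise (0 = noiseless).
#' @param assay_strength_range Range (U) the assay certificate strength is
#'   drawn from uniformly.
#' @param assay_to_measurement_days Range of signed day offsets from assay to
#'   measurement date.
#' @param error_rates Named rates in \[0, 1\] (summing to at most 1) for the
#'   injected error kinds `unit_confusion`, `transcription`, `wrong_plaque`,
#'   `activity_mismatch`.
#' @param activity_mismatch_pct Percent rescaling applied by the
#'   `activity_mismatch` error (default -6.8, the worst case observed: a
#'   mismatch between ordered and delivered seed activity).
#' @param constants A [plaque_constants()] object used to synthesise readings.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(type_factors = default_type_factors(),
                              reading_noise_sd = 0.01,
                              assay_strength_range = c(35, 120),
                              assay_to_measurement_days = c(-5, 45),
                              error_rates = c(unit_confusion = 0,
                                              transcription = 0,
                                              wrong_plaque = 0,
                                              activity_mismatch = 0),
                              activity_mismatch_pct = -6.8,
                              constants = plaque_constants()) {
  stopifnot(is.data.frame(type_factors),
            all(c("plaque_type", "mean_factor", "cv_pct") %in%
                  names(type_factors)),
            all(type_factors$mean_factor > 0),
            all(type_factors$cv_pct >= 0),
            reading_noise_sd >= 0,
            length(assay_strength_range) == 2,
            all(assay_strength_range > 0),
            all(error_rates >= 0), all(error_rates <= 1),
            sum(error_rates) <= 1)
  check_constants(constants)
  structure(
    list(type_factors = tibble::as_tibble(type_factors),
         reading_noise_sd = reading_noise_sd,
         assay_strength_range = assay_strength_range,
         assay_to_measurement_days = assay_to_measurement_days,
         error_rates = error_rates,
         activity_mismatch_pct = activity_mismatch_pct,
         constants = constants),
    class = "simulation_config"
  )
}

#' Study-condition calibration factors per plaque type
#'
#' EP917: mean factor 0.353, CV 3.29% (56 plaques); COMS types: the
#' published per-type means and CVs.
#'
#' @return A tibble with `plaque_type`, `mean_factor`, `cv_pct`.
#' @export
default_type_factors <- function() {
  coms <- tibble::tibble(
    plaque_type = c("COMS10", "COMS12", "COMS12N", "COMS14", "COMS14N",
                    "COMS16", "COMS16N", "COMS18", "COMS18N", "COMS20",
                    "COMS20N"),
    mean_factor = c(0.264, 0.256, 0.252, 0.264, 0.254, 0.262, 0.245,
                    0.250, 0.254, 0.234, 0.243),
    cv_pct = c(2.6, 2.6, 2.4, 3.2, 4.1, 3.8, 2.7, 1.5, 3.3, 1.9, 2.0)
  )
  dplyr::bind_rows(
    tibble::tibble(plaque_type = "EP917", mean_factor = 0.353, cv_pct = 3.29),
    coms
  )
}

#' Simulate plaque records with known ground truth
#'
#' Emulates the measurement process: draw each plaque's true calibration
#' factor from its type's normal distribution, draw an assay certificate
#' (strength and date), decay it to the measurement date, and synthesise
#' four angle readings whose expected mean is
#' `true_factor * decayed_strength / u_per_mci`, each perturbed by
#' independent multiplicative lognormal noise. The returned tibble is a
#' valid worksheet input carrying the ground truth (`true_factor`,
#' `error_kind = "none"`) alongside.
#'
#' @param n Number of records.
#' @param plaque_type Plaque type label(s), recycled to length `n`; must
#'   appear in the config's `type_factors`.
#' @param config A [simulation_config()].
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return A records tibble with ground-truth columns.
#' @examples
#' simulate_records(3, "EP917", seed = 1)
#' @export
simulate_records <- function(n, plaque_type = "EP917",
                             config = simulation_config(), seed = NULL) {
  stopifnot(inherits(config, "simulation_config"), n >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  types <- rep_len(plaque_type, n)
  idx <- match(types, config$type_factors$plaque_type)
  if (anyNA(idx)) {
    stop("unknown plaque type(s): ",
         paste(unique(types[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  mu <- config$type_factors$mean_factor[idx]
  sigma <- mu * config$type_factors$cv_pct[idx] / 100
  true_factor <- stats::rnorm(n, mu, sigma)
  true_factor <- pmax(true_factor, 0.05 * mu) # guard absurd tail draws

  cons <- config$constants
  assay_strength <- stats::runif(n, config$assay_strength_range[1],
                                 config$assay_strength_range[2])
  assay_date <- as.Date("2012-01-01") +
    sample.int(365, n, replace = TRUE) - 1L
  offset <- sample(seq(config$assay_to_measurement_days[1],
                       config$assay_to_measurement_days[2]),
                   n, replace = TRUE)
  measurement_date <- assay_date + offset
  decayed <- assay_strength * 2^(-offset / cons$half_life_days)

  target_activity <- true_factor * decayed / cons$u_per_mci
  noise <- matrix(
    stats::rlnorm(4L * n,
                  meanlog = -config$reading_noise_sd^2 / 2,
                  sdlog = config$reading_noise_sd),
    nrow = n)
  readings <- target_activity * noise

  cap <- stats::setNames(plaque_capacities()$capacity,
                         plaque_capacities()$plaque_type)
  n_seeds <- unname(cap[types])
  n_seeds[is.na(n_seeds)] <- 17L

  tibble::tibble(
    plaque_id = sprintf("SIM%04d", seq_len(n)),
    plaque_type = types,
    n_seeds = as.integer(n_seeds),
    assay_date = assay_date,
    assay_strength_u = assay_strength,
    measurement_date = measurement_date,
    reading_0 = readings[, 1],
    reading_90 = readings[, 2],
    reading_180 = readings[, 3],
    reading_270 = readings[, 4],
    true_factor = true_factor,
    error_kind = "none"
  )
}

#' Inject a known error into clean records
#'
#' Corrupts records the way ordering and transcription mistakes corrupt real
#' worksheets, so the action limit's sensitivity can be measured against
#' ground truth:
#' \describe{
#'   \item{unit_confusion}{assay strength in U mistakenly treated as mCi:
#'     multiplied by 1/0.787, a ~27% shift.}
#'   \item{transcription}{two adjacent digits of the assay strength swapped.}
#'   \item{wrong_plaque}{the readings are regenerated as if a plaque of a
#'     different type (different true factor) had been shipped.}
#'   \item{activity_mismatch}{all readings rescaled by
#'     `config$activity_mismatch_pct` percent (ordered vs delivered
#'     activity mismatch).}
#' }
#'
#' @param records A records tibble from [simulate_records()].
#' @param error_kind One of the four kinds above.
#' @param config A [simulation_config()].
#' @param seed Optional integer seed (used by the stochastic kinds).
#' @return The corrupted records tibble, `error_kind` updated.
#' @export
inject_error <- function(records,
                         error_kind = c("unit_confusion", "transcription",
                                        "wrong_plaque", "activity_mismatch"),
                         config = simulation_config(), seed = NULL) {
  error_kind <- match.arg(error_kind)
  if (!is.null(seed)) withr::local_seed(seed)
  out <- records
  reading_cols <- c("reading_0", "reading_90", "reading_180", "reading_270")
  if (error_kind == "unit_confusion") {
    out$assay_strength_u <- out$assay_strength_u /
      config$constants$mci_per_u
  } else if (error_kind == "transcription") {
    out$assay_strength_u <- vapply(out$assay_strength_u, swap_adjacent_digits,
                                   numeric(1))
  } else if (error_kind == "wrong_plaque") {
    for (i in seq_len(nrow(out))) {
      others <- setdiff(config$type_factors$plaque_type, out$plaque_type[i])
      wrong <- sample(others, 1L)
      j <- match(wrong, config$type_factors$plaque_type)
      ratio <- config$type_factors$mean_factor[j] /
        config$type_factors$mean_factor[
          match(out$plaque_type[i], config$type_factors$plaque_type)]
      out[i, reading_cols] <- out[i, reading_cols] * ratio
    }
  } else { # activity_mismatch
    scale <- 1 + config$activity_mismatch_pct / 100
    for (cl in reading_cols) out[[cl]] <- out[[cl]] * scale
  }
  out$error_kind <- error_kind
  out
}

# swap the two adjacent significant digits that change the value most
# realistically: pick a random adjacent pair in the digit string
swap_adjacent_digits <- function(x) {
  s <- sub("0+$", "", sprintf("%.2f", x))
  chars <- strsplit(s, "")[[1]]
  digit_pos <- which(chars %in% as.character(0:9))
  pairs <- digit_pos[which(diff(digit_pos) == 1)]
  if (length(pairs) == 0) return(x)
  p <- if (length(pairs) == 1) pairs else sample(pairs, 1L)
  tmp <- chars[p]
  chars[p] <- chars[p + 1L]
  chars[p + 1L] <- tmp
  as.numeric(paste(chars, collapse = ""))
}

#' Measure flag sensitivity on a simulated cohort
#'
#' Generates a clean cohort, evaluates it against the configured true type
#' factors, and records the false-positive rate of the action limit; then,
#' for each requested error kind, corrupts a fresh clean cohort and records
#' the detection rate (fraction of corrupted records flagged).
#'
#' @param config A [simulation_config()].
#' @param n_records Cohort size per condition.
#' @param plaque_type Plaque type to simulate.
#' @param error_kinds Character vector of kinds from [inject_error()].
#' @param limits A [qa_limits()] object.
#' @param seed Integer seed; all randomness derives from it.
#' @return A tibble with one row per condition (`"clean"` plus each error
#'   kind): `condition`, `n`, `flag_rate_pct` and its role
#'   (`"false_positive"` for clean, `"detection"` otherwise).
#' @export
sensitivity_study <- function(config = simulation_config(), n_records = 500,
                              plaque_type = "EP917",
                              error_kinds = c("unit_confusion",
                                              "transcription",
                                              "wrong_plaque",
                                              "activity_mismatch"),
                              limits = qa_limits(), seed = NULL) {
  stopifnot(n_records >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  true_means <- config$type_factors[c("plaque_type", "mean_factor")]
  flag_rate <- function(recs) {
    ev <- evaluate_worksheet(recs, group_mean_factor = true_means,
                             constants = config$constants, limits = limits)
    100 * mean(ev$flag_action_limit)
  }
  clean <- simulate_records(n_records, plaque_type, config)
  rows <- list(tibble::tibble(condition = "clean", n = n_records,
                              flag_rate_pct = flag_rate(clean),
                              rate_type = "false_positive"))
  for (kind in error_kinds) {
    base <- simulate_records(n_records, plaque_type, config)
    corrupted <- inject_error(base, kind, config)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      condition = kind, n = n_records,
      flag_rate_pct = flag_rate(corrupted),
      rate_type = "detection")
  }
  dplyr::bind_rows(rows)
}

#' Closed-form false-positive rate of the action limit
#'
#' Under a normal model for the calibration-factor dispersion, a clean
#' plaque of a type with coefficient of variation `cv_pct` is flagged at a
#' symmetric action limit with probability `2 * (1 - pnorm(limit / cv))`.
#' Used as the analytic cross-check for [sensitivity_study()].
#'
#' @param cv_pct Coefficient of variation of the type's factors, percent.
#' @param action_limit_pct The action limit, percent.
#' @return Expected false-positive rate, percent.
#' @examples
#' false_positive_rate_normal(3.29, 5) # ~12.9
#' @export
false_positive_rate_normal <- function(cv_pct, action_limit_pct = 5) {
  stopifnot(cv_pct > 0, action_limit_pct > 0)
  200 * (1 - stats::pnorm(action_limit_pct / cv_pct))
}
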