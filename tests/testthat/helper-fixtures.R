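# Shared fixtures: the ten-plaque EP917 worksheet and the three-plaque
# seed-contribution table, plus a writer for ad-hoc worksheet CSVs.

table1_records <- function() {
  example_data("worksheet")
}

table1_printed <- function() {
  tibble::tibble(
    plaque_id = as.character(1:10),
    measured_strength_u = c(25.78, 17.84, 13.43, 11.73, 14.21,
                            21.46, 23.12, 21.88, 19.78, 16.64),
    decayed_strength_u = c(75.07, 47.73, 37.87, 34.37, 40.26,
                           62.37, 68.50, 59.82, 54.18, 49.21),
    cal_factor = c(0.343, 0.374, 0.355, 0.341, 0.353,
                   0.344, 0.338, 0.366, 0.365, 0.338),
    deviation_pct = c(-2.8, 5.9, 0.4, -3.3, 0.0, -2.6, -4.4, 3.6, 3.4, -4.3)
  )
}

seed_activity_table <- function() {
  example_data("seed_contribution")
}

write_temp_worksheet <- function(df, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = env)
  readr::write_csv(df, path)
  path
}

noiseless_config <- function(cv_pct = 0) {
  simulation_config(
    type_factors = tibble::tibble(
      plaque_type = c("EP917", "COMS14"),
      mean_factor = c(0.353, 0.264),
      cv_pct = cv_pct
    ),
    reading_noise_sd = 0
  )
}
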