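test_that("noiseless simulation round-trips the configured factor exactly", {
  cfg <- noiseless_config(cv_pct = 0)
  rec <- simulate_records(5, "EP917", cfg, seed = 1)
  ev <- evaluate_worksheet(rec, group_mean_factor = 0.353,
                           constants = cfg$constants)
  expect_equal(ev$cal_factor, rep(0.353, 5), tolerance = 1e-12)
  expect_equal(ev$deviation_pct, rep(0, 5), tolerance = 1e-9)
  expect_false(any(ev$flag_action_limit))
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_records(20, "EP917", seed = 99)
  b <- simulate_records(20, "EP917", seed = 99)
  expect_identical(a, b)
  c <- simulate_records(20, "EP917", seed = 100)
  expect_false(identical(a$reading_0, c$reading_0))
  expect_error(simulate_records(3, "NOT_A_PLAQUE"), "unknown plaque type")
})

test_that("a large clean cohort reproduces the configured dispersion", {
  rec <- simulate_records(1000, "EP917", seed = 202)
  ev <- evaluate_worksheet(rec, group_mean_factor = 0.353)
  cv <- 100 * sd(ev$cal_factor) / mean(ev$cal_factor)
  expect_equal(cv, 3.29, tolerance = 0.5 / 3.29)
  expect_equal(mean(ev$cal_factor), 0.353, tolerance = 0.01)
  # the default angle noise keeps the reading spread under the 4% limit
  expect_lt(median(ev$spread_pct), 4)
})

test_that("error injection shifts records by the intended magnitudes", {
  cfg <- noiseless_config(cv_pct = 0)
  clean <- simulate_records(4, "EP917", cfg, seed = 3)

  uc <- inject_error(clean, "unit_confusion", cfg)
  ev <- evaluate_worksheet(uc, group_mean_factor = 0.353,
                           constants = cfg$constants)
  # factor shrinks by 0.787: deviation magnitude ~ 21.3% down, i.e. the
  # 27% unit-confusion shift seen from the other side of the ratio
  expect_equal(0.353 / ev$cal_factor - 1, rep(1 / 0.787 - 1, 4),
               tolerance = 1e-9)
  expect_true(all(abs(ev$deviation_pct) > 5))

  none <- inject_error(clean, "activity_mismatch",
                       simulation_config(activity_mismatch_pct = 0,
                                         reading_noise_sd = 0))
  expect_equal(none$reading_0, clean$reading_0)

  worst <- inject_error(clean, "activity_mismatch", cfg)
  ev_w <- evaluate_worksheet(worst, group_mean_factor = 0.353,
                             constants = cfg$constants)
  expect_equal(ev_w$deviation_pct, rep(-6.8, 4), tolerance = 1e-9)
  expect_true(all(ev_w$flag_action_limit))

  tr <- inject_error(clean, "transcription", cfg, seed = 8)
  # a swap of two unequal adjacent digits changes the certificate value
  expect_true(any(tr$assay_strength_u != clean$assay_strength_u))

  wp <- inject_error(clean, "wrong_plaque", cfg, seed = 9)
  expect_false(any(wp$reading_0 == clean$reading_0))

  expect_error(inject_error(clean, "gremlins"))
})

test_that("detection and false-positive rates behave as the error model predicts", {
  cfg0 <- noiseless_config(cv_pct = 0)
  st <- sensitivity_study(cfg0, n_records = 50,
                          error_kinds = c("unit_confusion",
                                          "activity_mismatch"),
                          seed = 17)
  expect_equal(st$flag_rate_pct[st$condition == "clean"], 0)
  expect_equal(st$flag_rate_pct[st$condition == "unit_confusion"], 100)
  expect_equal(st$flag_rate_pct[st$condition == "activity_mismatch"], 100)

  # detection is monotone nondecreasing in the injected magnitude
  rates <- vapply(c(0.5, 3, 5.5, 10, 30), function(mag) {
    cfg <- simulation_config(
      type_factors = cfg0$type_factors, reading_noise_sd = 0,
      activity_mismatch_pct = -mag)
    st <- sensitivity_study(cfg, n_records = 30,
                            error_kinds = "activity_mismatch", seed = 23)
    st$flag_rate_pct[st$condition == "activity_mismatch"]
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("the clean false-positive rate matches the normal-tail closed form", {
  expect_equal(false_positive_rate_normal(3.29, 5),
               200 * (1 - pnorm(5 / 3.29)))
  cfg <- simulation_config()
  n <- 10000
  st <- sensitivity_study(cfg, n_records = n,
                          error_kinds = character(0), seed = 29)
  observed <- st$flag_rate_pct[st$condition == "clean"]
  # the evaluated factor carries the type CV plus the mean-of-four-readings
  # noise, added in quadrature
  cv_eff <- sqrt(3.29^2 + (100 * cfg$reading_noise_sd)^2 / 4)
  expected <- false_positive_rate_normal(cv_eff, 5)
  mc_sigma <- 100 * sqrt(expected / 100 * (1 - expected / 100) / n)
  expect_lt(abs(observed - expected), 3 * mc_sigma)
})
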