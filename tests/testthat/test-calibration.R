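test_that("four-angle averaging computes mean and spread and flags poor centering", {
  same <- average_readings(20.30, 20.30, 20.30, 20.30)
  expect_equal(same$mean_activity_mci, 20.30)
  expect_equal(same$spread_pct, 0)
  expect_true(same$spread_ok)

  ok <- average_readings(20.0, 20.4, 20.2, 20.6)
  expect_equal(ok$mean_activity_mci, 20.30)
  expect_equal(ok$spread_pct, 100 * 0.6 / 20.3)
  expect_true(ok$spread_ok)

  wide <- average_readings(19.0, 20.0, 20.5, 21.0)
  expect_equal(wide$spread_pct, 100 * 2 / 20.125)
  expect_false(wide$spread_ok)

  expect_error(average_readings(0, 0, 0, 0), "zero")
  expect_error(average_readings(-1, 1, 1, 1), "non-negative")

  # alternative denominator convention
  alt <- average_readings(19.0, 20.0, 20.5, 21.0, spread_metric = "min")
  expect_equal(alt$spread_pct, 100 * 2 / 19)
})

test_that("calibration factor and deviation reproduce worksheet arithmetic", {
  expect_equal(round(calibration_factor(25.78, 75.07), 3), 0.343)
  expect_equal(round(calibration_factor(17.84, 47.73), 3), 0.374)
  expect_equal(calibration_factor(42, 42), 1)
  expect_error(calibration_factor(10, 0), "positive")
  expect_error(calibration_factor(0, 10), "positive")

  expect_equal(round(deviation_from_mean(0.374, 0.353), 1), 5.9)
  expect_equal(round(deviation_from_mean(0.343, 0.353), 1), -2.8)
  expect_identical(deviation_from_mean(0.353, 0.353), 0)
  expect_error(deviation_from_mean(0.3, 0), "positive")
})

test_that("evaluating the worksheet chains the full verification pipeline", {
  ev <- evaluate_worksheet(table1_records(), group_mean_factor = 0.353)
  expect_s3_class(ev, "plaque_calibration")
  expect_equal(round(ev$decayed_strength_u[1], 2), 75.07, tolerance = 0.011)
  expect_equal(round(ev$measured_strength_u[1], 2), 25.78)
  expect_equal(round(ev$cal_factor[1], 3), 0.343)
  expect_equal(round(ev$deviation_pct[1], 1), -2.8, tolerance = 0.11)
  # the +5.9% plaque is the only one beyond the action limit
  expect_identical(which(ev$flag_action_limit), 2L)

  # constructed identity: measured strength equals decayed assay strength
  cons <- plaque_constants()
  ident <- tibble::tibble(
    plaque_id = "I", plaque_type = "EP917", n_seeds = 17,
    assay_date = as.Date("2012-01-01"), assay_strength_u = 60,
    measurement_date = as.Date("2012-01-01"),
    activity_mci = 60 / cons$u_per_mci)
  ev1 <- evaluate_worksheet(ident, group_mean_factor = 1)
  expect_equal(ev1$cal_factor, 1)
  expect_equal(ev1$deviation_pct, 0)
})

test_that("group means can come from a constant, a table, or the records themselves", {
  rec <- table1_records()
  ev_self <- evaluate_worksheet(rec)
  expect_equal(unique(ev_self$group_mean_factor), mean(ev_self$cal_factor))
  # mean of deviations against the group's own mean vanishes
  expect_equal(mean(ev_self$deviation_pct), 0, tolerance = 1e-9)

  tbl <- tibble::tibble(plaque_type = "EP917", mean_factor = 0.353)
  ev_tbl <- evaluate_worksheet(rec, group_mean_factor = tbl)
  ev_num <- evaluate_worksheet(rec, group_mean_factor = 0.353)
  expect_equal(ev_tbl$deviation_pct, ev_num$deviation_pct)
})

test_that("plan-vs-assay cross-checks flag unit confusion but pass small drift", {
  rec <- table1_records()[1:3, ]
  rec$plan_date <- rec$assay_date
  # plaque 1: plan == assay; plaque 2: unit confusion (x 1/0.787);
  # plaque 3: 3% high, inside the 5% limit
  rec$plan_strength_u <- rec$assay_strength_u * c(1, 1 / 0.787, 1.03)
  ev <- evaluate_worksheet(rec, group_mean_factor = 0.353)
  expect_identical(ev$flag_cross_check, c(FALSE, TRUE, FALSE))
  cc <- cross_check(ev)
  expect_equal(cc$strength_diff_pct[2], 100 * (1 / 0.787 - 1), tolerance = 1e-6)
  expect_identical(cc$flag_cross_check, c(FALSE, TRUE, FALSE))

  # no plan data: skipped with a notice, nothing flagged
  expect_message(out <- cross_check(evaluate_worksheet(table1_records())),
                 "skipped")
  expect_equal(nrow(out), 0)
})

test_that("the calibration factor is scale invariant and flags are monotone", {
  withr::with_seed(5, {
    for (i in 1:10) {
      m <- runif(1, 10, 30); d <- runif(1, 30, 90); k <- runif(1, 0.1, 10)
      expect_equal(calibration_factor(k * m, k * d), calibration_factor(m, d))
    }
  })
  limits <- qa_limits()
  devs <- sort(abs(c(-7.2, 4.9, 5.1, 0, 6.8, 2.2)))
  flagged <- devs > limits$action_limit_pct
  # once a magnitude is flagged, every larger magnitude is flagged
  expect_true(all(diff(as.integer(flagged)) >= 0))
})

test_that("full-precision and printed-precision factors agree at 3 dp", {
  ev <- evaluate_worksheet(table1_records(), group_mean_factor = 0.353)
  printed <- table1_printed()
  rounded_chain <- round(printed$measured_strength_u /
                           printed$decayed_strength_u, 3)
  expect_equal(round(ev$cal_factor, 3), rounded_chain)
  expect_equal(round(ev$cal_factor, 3), printed$cal_factor)
})

test_that("tidy and glance summarise an evaluated worksheet", {
  ev <- evaluate_worksheet(table1_records(), group_mean_factor = 0.353)
  td <- tidy(ev)
  expect_true(all(c("plaque_id", "cal_factor", "deviation_pct",
                    "flag_action_limit") %in% names(td)))
  gl <- glance(ev)
  expect_equal(gl$n_plaques, 10)
  expect_equal(gl$n_flag_action, 1)
  expect_equal(gl$mean_cal_factor, mean(ev$cal_factor))
})
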