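test_that("the bundled worksheet reads into ten validated records", {
  rec <- table1_records()
  expect_equal(nrow(rec), 10)
  expect_true(all(rec$plaque_type == "EP917"))
  expect_equal(rec$n_seeds, c(17L, 17L, 15L, 15L, 6L, 17L, 17L, 17L, 17L, 17L))
  expect_s3_class(rec$assay_date, "Date")
  expect_equal(rec$assay_strength_u[1], 115.60)
  expect_true(all(rec$provenance == "pre-averaged"))
})

test_that("file- and row-level problems are reported with context", {
  empty <- write_temp_worksheet(table1_records()[0, ])
  expect_error(read_worksheet(empty), "no records")

  df <- tibble::tibble(plaque_id = "1", plaque_type = "EP917",
                       n_seeds = 17, assay_date = "1/1/2012",
                       assay_strength_u = 50)
  expect_error(read_worksheet(write_temp_worksheet(df)),
               "measurement_date")

  # capacity violation: 18 seeds in a 17-slot EP917, diagnostic names row+column
  over <- tibble::tibble(
    plaque_id = "X", plaque_type = "EP917", n_seeds = 18,
    assay_date = "1/1/2012", assay_strength_u = 50,
    measurement_date = "1/5/2012", activity_mci = 14)
  expect_warning(read_worksheet(write_temp_worksheet(over)),
                 "row 1, column n_seeds.*capacity of 17")

  unknown <- dplyr::mutate(over, n_seeds = 10, plaque_type = "COMS99")
  expect_warning(read_worksheet(write_temp_worksheet(unknown)),
                 "row 1, column plaque_type")
})

test_that("records round-trip through CSV unchanged", {
  rec <- table1_records()
  path <- write_temp_worksheet(
    dplyr::mutate(rec, assay_date = format(assay_date, "%m/%d/%Y"),
                  measurement_date = format(measurement_date, "%m/%d/%Y")))
  back <- read_worksheet(path)
  for (col in c("plaque_id", "n_seeds", "assay_strength_u", "activity_mci")) {
    expect_identical(back[[col]], rec[[col]])
  }
  expect_identical(back$assay_date, rec$assay_date)
  expect_identical(back$measurement_date, rec$measurement_date)
})

test_that("four raw readings and pre-averaged activity are both accepted", {
  df <- tibble::tibble(
    plaque_id = c("A", "B"), plaque_type = "EP917", n_seeds = 17,
    assay_date = "1/1/2012", assay_strength_u = 60,
    measurement_date = "1/6/2012",
    reading_0 = c(15.0, NA), reading_90 = c(15.2, NA),
    reading_180 = c(14.8, NA), reading_270 = c(15.0, NA),
    activity_mci = c(NA, 15.0))
  rec <- read_worksheet(write_temp_worksheet(df))
  expect_identical(rec$provenance, c("angles", "pre-averaged"))
  ev <- evaluate_worksheet(rec, group_mean_factor = 0.353)
  expect_equal(ev$mean_activity_mci, c(15, 15))
})

test_that("the rendered worksheet carries printed precision and flag markers", {
  ev <- evaluate_worksheet(table1_records(), group_mean_factor = 0.353)
  path <- withr::local_tempfile(fileext = ".csv")
  out <- write_worksheet(ev, path)
  expect_identical(out$cal_factor[1], "0.343")
  expect_identical(out$decayed_strength_u[1], "75.07")
  # only plaque 2 (deviation +5.9%) carries the action-limit marker
  expect_identical(which(out$flagged == "*"), 2L)
  rendered <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(rendered), 10)

  # empty result set renders a header-only file
  empty <- ev[0, ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_worksheet(empty, path2)
  expect_equal(length(readLines(path2)), 1L)

  expect_error(write_worksheet(table1_records(), path), "evaluate")
})
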