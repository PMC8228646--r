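test_that("keyword filter includes pneumonia variants and excludes lookalikes", {
  recs <- tibble::tibble(reason_text = c(
    "Bronchopneumonia",           # matches "monia"
    "PNEUMONIA",                  # case-insensitive
    "brpn ?",                     # matches "brpn"
    "BPN severe",                 # matches "bpn"
    "pcp suspected",              # matches "pcp"
    "aspiration pneumonia",       # excluded by "asp"
    "chemical pneumonitis",       # excluded by "chem"
    "pneumothorax",               # excluded
    "asthma",                     # no inclusion match
    ""))                          # empty never matches
  kept <- filter_pneumonia(recs)
  expect_equal(kept$reason_text,
               c("Bronchopneumonia", "PNEUMONIA", "brpn ?", "BPN severe",
                 "pcp suspected"))
})

test_that("filter is idempotent, order-preserving and handles empty input", {
  recs <- tibble::tibble(reason_text = c("pneumonia b", "pneumonia a",
                                         "fracture"))
  once <- filter_pneumonia(recs)
  expect_identical(filter_pneumonia(once), once)
  expect_equal(once$reason_text, c("pneumonia b", "pneumonia a"))
  empty <- filter_pneumonia(recs[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
})

test_that("exclusion takes precedence even when an inclusion term matches", {
  recs <- tibble::tibble(reason_text = c("pneumonia after aspiration",
                                         "chem exposure pneumonia"))
  expect_equal(nrow(filter_pneumonia(recs)), 0)
})

test_that("admission dates are reconstructed as discharge minus length of stay", {
  recs <- tibble::tibble(
    admission_date = as.Date(c(NA, NA, "2010-01-02", NA)),
    discharge_date = as.Date(c("2010-03-10", "2010-03-10", "2010-01-05", NA)),
    length_of_stay = c(4, NA, 3, NA))
  out <- reconstruct_admission_dates(recs)
  expect_equal(out$admission_date[1], as.Date("2010-03-06"))
  expect_equal(out$date_status,
               c("reconstructed", "needs_imputation", "observed", "excluded"))
  # already-present dates untouched, LOS 0 means same-day admission
  expect_equal(out$admission_date[3], as.Date("2010-01-02"))
  same_day <- reconstruct_admission_dates(tibble::tibble(
    admission_date = as.Date(NA), discharge_date = as.Date("2011-06-01"),
    length_of_stay = 0))
  expect_equal(same_day$admission_date, as.Date("2011-06-01"))
  expect_error(reconstruct_admission_dates(tibble::tibble(
    admission_date = as.Date(NA), discharge_date = as.Date("2011-06-01"),
    length_of_stay = -1)), "non-negative")
})

test_that("daily aggregation zero-fills, counts, and checks meteorology coverage", {
  met <- tibble::tibble(date = seq(as.Date("2008-01-01"),
                                   as.Date("2008-01-10"), by = "day"),
                        mean_temp = 21, rh = 67,
                        min_temp = 15, max_temp = 28)
  recs <- tibble::tibble(admission_date = as.Date(
    c("2008-01-05", "2008-01-05", "2008-01-05", "2008-01-02", "2007-12-30")))
  expect_message(
    daily <- aggregate_daily(recs, met, as.Date("2008-01-01"),
                             as.Date("2008-01-10")),
    "dropped")
  expect_equal(nrow(daily), 10)
  expect_equal(daily$count[daily$date == as.Date("2008-01-05")], 3L)
  expect_equal(daily$count[daily$date == as.Date("2008-01-03")], 0L)
  expect_equal(sum(daily$count), 4L)       # out-of-range record not counted
  expect_equal(attr(daily, "n_dropped"), 1L)
  expect_true(all(diff(daily$date) == 1))
  expect_equal(daily$dtr, rep(13, 10))     # max - min
  # gap in meteorology is an error naming the missing dates
  expect_error(
    aggregate_daily(recs, met[-3, ], as.Date("2008-01-01"),
                    as.Date("2008-01-10")),
    "2008-01-03")
})

test_that("record readers and writers round-trip through delimited text", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  recs <- tibble::tibble(reason_text = c("pneumonia", "asthma"),
                         admission_date = as.Date(c("2010-01-01", NA)),
                         discharge_date = as.Date(c("2010-01-04", "2010-02-01")),
                         length_of_stay = c(3L, NA))
  readr::write_csv(recs, tmp)
  back <- read_admission_records(tmp)
  expect_equal(back$admission_date, recs$admission_date)
  expect_equal(back$length_of_stay, recs$length_of_stay)

  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  daily <- sim_small_study(60, seed = 9)
  write_daily_series(daily, tmp2)
  back2 <- readr::read_tsv(tmp2, show_col_types = FALSE)
  expect_equal(back2$count, daily$count)
  expect_equal(back2$mean_temp, daily$mean_temp, tolerance = 1e-9)
})
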