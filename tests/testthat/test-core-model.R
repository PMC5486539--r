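test_that("threshold construction validates its invariants", {
  th <- thresholds()
  expect_equal(th$torpor_cutoff, 32)
  expect_equal(th$hyperthermia_cutoff, 40)
  expect_error(thresholds(torpor_cutoff = 41), "below")
  expect_error(thresholds(subcutaneous_offset = -1), "positive")
})

test_that("route correction lowers only the activity threshold, once", {
  th <- thresholds()
  sc <- effective_thresholds(th, "subcutaneous")
  expect_equal(sc$hyperthermia_cutoff, 38)
  expect_equal(sc$torpor_cutoff, 32)
  ip <- effective_thresholds(th, "intraperitoneal")
  expect_identical(ip, th)
  ## idempotent for intraperitoneal
  expect_identical(effective_thresholds(ip, "intraperitoneal"), th)
  ## a measured 1.8 C offset would give 38.2
  expect_equal(
    effective_thresholds(thresholds(subcutaneous_offset = 1.8),
                         "subcutaneous")$hyperthermia_cutoff, 38.2)
})

test_that("week-of-year uses 7-day blocks anchored at Jan 1", {
  expect_equal(week_of_year(as.Date("2013-01-01")), 1L)
  expect_equal(week_of_year(as.Date("2013-01-08")), 2L)
  ## Aug 27 (day 239 in a non-leap year) falls in week 35, the last week
  ## of August: floor(238/7) + 1
  expect_equal(week_of_year(as.Date("2013-08-27")), 35L)
  ## non-decreasing over a year and covering 1..53 exactly
  days <- seq(as.Date("2013-01-01"), as.Date("2013-12-31"), by = 1)
  wk <- week_of_year(days)
  expect_true(all(diff(wk) >= 0))
  expect_identical(sort(unique(wk)), 1:53)
})

test_that("weeks prior to hibernation anchor week 0 at onset", {
  on <- as.Date("2013-09-20")
  expect_equal(weeks_prior_to_hibernation(on, on), 0L)
  expect_equal(weeks_prior_to_hibernation(on - 6, on), 0L)
  expect_equal(weeks_prior_to_hibernation(on - 7, on), -1L)
  expect_equal(weeks_prior_to_hibernation(on - 10, on), -1L)
  expect_error(weeks_prior_to_hibernation(on + 1, on), "after")
})

test_that("logger CSV reading parses, deduplicates and filters", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,tb",
               "2013-06-01 12:00:00,37.0",
               "2013-06-01 13:04:10,36.5",
               "2013-06-01 14:08:20,38.0"), f)
  m <- animal_meta("A1", "female", "adult", "field", "intraperitoneal",
                   2013, "mast")
  ## too short a span must be rejected
  expect_error(read_logger_csv(f, m), "21")

  ## a month of hourly-cadence data with one duplicate and one bad row
  ts <- as.POSIXct("2013-06-01 00:00:00", tz = "UTC") + 3850 * 0:700
  d <- data.frame(timestamp = format(ts, "%Y-%m-%d %H:%M:%S"),
                  tb = rep(37, 701))
  d$tb[100] <- 99   # physically impossible, must be dropped
  d <- rbind(d, d[5, ])  # duplicated timestamp, keep first
  write.csv(d, f, row.names = FALSE)
  expect_warning(expect_warning(s <- read_logger_csv(f, m),
                                "duplicated"), "implausible")
  expect_equal(nrow(s$records), 700)
  expect_s3_class(s, "tb_series")
})

test_that("a written series round-trips through CSV unchanged", {
  r <- mast_female(7)
  f <- withr::local_tempfile(fileext = ".csv")
  write_tb_csv(r$series, f)
  back <- read_logger_csv(f, r$series$meta)
  expect_equal(back$records$tb, r$series$records$tb)
  expect_equal(as.numeric(back$records$timestamp),
               as.numeric(r$series$records$timestamp))
})

test_that("logger-dialect timestamps (DD.MM.YY) parse", {
  f <- withr::local_tempfile(fileext = ".csv")
  ts <- as.POSIXct("2013-06-01 00:00:00", tz = "UTC") + 3850 * 0:600
  write.csv(data.frame(timestamp = format(ts, "%d.%m.%y %H:%M:%S"),
                       tb = 37), f, row.names = FALSE)
  m <- animal_meta("A1", "male", "adult", "field", "intraperitoneal",
                   2013, "mast")
  s <- read_logger_csv(f, m)
  expect_equal(nrow(s$records), 601)
  expect_equal(format(s$records$timestamp[1], "%Y-%m-%d"), "2013-06-01")
})

test_that("metadata reader enforces mast consistency within site-year", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(animal_id = c("a", "b"), sex = "female",
                       age_class = "adult", site = "field",
                       implant_route = "intraperitoneal", year = 2013,
                       mast = c("mast", "failure")), f, row.names = FALSE)
  expect_error(read_meta_csv(f), "inconsistent mast")
  write.csv(data.frame(animal_id = c("a", "b"), sex = "female",
                       age_class = "adult", site = "field",
                       implant_route = "intraperitoneal", year = 2013,
                       mast = "mast"), f, row.names = FALSE)
  metas <- read_meta_csv(f)
  expect_length(metas, 2)
  expect_s3_class(metas[[1]], "animal_meta")
})
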