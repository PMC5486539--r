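test_that("sample classification uses strict cutoffs on both sides", {
  th <- thresholds()
  expect_equal(classify_sample(31.5, th), "torpor")
  expect_equal(classify_sample(40.5, th), "hyperthermia")
  expect_equal(classify_sample(32.0, th), "euthermia")
  expect_equal(classify_sample(40.0, th), "euthermia")
  expect_equal(classify_sample(c(10, 37, 41), th),
               c("torpor", "euthermia", "hyperthermia"))
})

.series_from_tb <- function(tb, iv = 3850, gap_after = integer()) {
  ts <- as.POSIXct("2013-06-01 00:00:00", tz = "UTC") + iv * seq_along(tb)
  if (length(gap_after))
    for (g in gap_after) ts[(g + 1):length(ts)] <-
      ts[(g + 1):length(ts)] + 3 * 3600
  m <- animal_meta("T1", "male", "adult", "field", "intraperitoneal",
                   2013, "mast")
  tb_series(m, data.frame(timestamp = ts, tb = tb), iv, validate = FALSE)
}

test_that("bout assembly follows run-length, duration and gap rules", {
  ## E,T,T,T,E: one short torpor bout of 3 intervals
  s <- .series_from_tb(c(37, 30, 30, 30, 37))
  b <- assemble_bouts(s)
  tor <- b[b$state == "torpor", ]
  expect_equal(nrow(tor), 1)
  expect_equal(tor$duration_h, 3 * 3850 / 3600, tolerance = 1e-9)
  expect_equal(tor$kind, "short")

  ## 30 h of torpor: multiday
  s2 <- .series_from_tb(rep(30, ceiling(30 * 3600 / 3850) + 1))
  b2 <- assemble_bouts(s2)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$kind, "multiday")

  ## a 3 h gap splits an otherwise continuous torpor run
  s3 <- .series_from_tb(c(30, 30, 30, 30), gap_after = 2)
  b3 <- assemble_bouts(s3)
  expect_equal(sum(b3$state == "torpor"), 2)
})

test_that("daily summaries compute interval-weighted hours and flags", {
  r <- mast_female(5)
  d <- r$daily
  expect_true(all(d$hours_above >= 0 & d$hours_above <= 24))
  expect_true(all(d$min_tb <= d$mean_tb & d$mean_tb <= d$max_tb))
  ## hours are multiples of the sampling interval
  expect_true(all(abs(d$hours_above / (3850 / 3600) -
                        round(d$hours_above / (3850 / 3600))) < 1e-6))
  ## a torpor day is flagged iff a sample fell below the cutoff
  cl <- classify_series(r$series)
  tor_dates <- unique(as.Date(cl$timestamp[cl$state == "torpor"], tz = "UTC"))
  expect_setequal(as.character(d$date[d$torpor_day]),
                  as.character(tor_dates))
})

test_that("hours above threshold are monotone in the cutoff", {
  r <- mast_female(5)
  h40 <- daily_summaries(r$series, th = thresholds())$hours_above
  h41 <- daily_summaries(r$series,
                         th = thresholds(hyperthermia_cutoff = 41))$hours_above
  expect_true(all(h41 <= h40))
})

test_that("hibernation onset picks the first fall multiday bout", {
  mk_bout <- function(start, dur_h, state = "torpor") {
    s <- as.POSIXct(start, tz = "UTC")
    data.frame(state = state, start = s, end = s + dur_h * 3600,
               duration_h = dur_h,
               kind = if (state == "torpor")
                 ifelse(dur_h >= 24, "multiday", "short") else NA)
  }
  b <- rbind(mk_bout("2013-06-15 10:00:00", 60),   # summer dormancy
             mk_bout("2013-09-20 09:00:00", 200))
  expect_equal(detect_hibernation_onset(b), as.Date("2013-09-20"))
  ## only short bouts: undetermined, not an error
  b2 <- mk_bout("2013-09-20 09:00:00", 5)
  expect_true(is.na(detect_hibernation_onset(b2)))
  ## custom window can admit the summer bout
  expect_equal(detect_hibernation_onset(b, as.Date("2013-06-01")),
               as.Date("2013-06-15"))
})

test_that("torpor day counts per week are order-invariant and exclude
           the onset week", {
  days <- toy_days(as.Date("2013-07-01") + 0:13, mean_tb = 37)
  days$torpor_day[c(2, 5, 9)] <- TRUE
  t1 <- torpor_days_per_week(days)
  expect_equal(t1$torpor_days[t1$week == 27], 2L)
  expect_equal(t1$torpor_days[t1$week == 28], 1L)
  perm <- days[sample(nrow(days)), ]
  expect_equal(torpor_days_per_week(perm), t1)
  ## with onset inside week 28, that week disappears (Jul 1 is the last
  ## day of block-week 26, so weeks 26 and 27 remain)
  t2 <- torpor_days_per_week(days, onset = as.Date("2013-07-10"))
  expect_equal(t2$week, c(26L, 27L))
})

test_that("classification recovers the generator's ground truth exactly", {
  fx <- default_cohort_analysis()
  ids <- names(fx$coh$series)[c(1, 10, 20, 30, 42)]
  for (id in ids) {
    s <- fx$coh$series[[id]]
    tr <- fx$coh$truths[[id]]
    cl <- classify_series(s)
    expect_identical(cl$state, tr$state)
    expect_equal(fx$onsets[[id]], tr$onset)
    d <- fx$daily[[id]]
    mm <- merge(d, tr$daily_hours_above, by = "date")
    expect_true(all(abs(mm$hours_above - mm$hours) <= 3850 / 3600 + 1e-9))
  }
  ## across the whole cohort, every onset is recovered exactly
  expect_true(all(!is.na(fx$onsets)))
  truth_onsets <- as.Date(vapply(fx$coh$truths, function(t)
    as.character(t$onset), ""))
  expect_equal(unname(fx$onsets), unname(truth_onsets))
})
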