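#' Classify body-temperature samples into thermal states
#'
#' A sample is \code{torpor} if Tb is strictly below the torpor cutoff
#' (32 degrees C by default), \code{hyperthermia} if strictly above the
#' hyperthermia cutoff (40 degrees C), and \code{euthermia} otherwise.
#' Both comparisons are strict: a reading exactly at 32.0 is euthermic, as
#' is one at 40.0.  At the 0.5 degree C logger resolution the strict/
#' non-strict choice is observationally equivalent, but it is fixed here
#' once and for all.  Thresholds must already be route-corrected (see
#' \code{\link{effective_thresholds}}).
#'
#' @param tb Numeric Tb values (degrees C).
#' @param th A \code{\link{thresholds}} object.
#' @return Character vector: "torpor", "euthermia" or "hyperthermia".
#' @export
classify_sample <- function(tb, th = thresholds()) {
  stopifnot(inherits(th, "thresholds"))
  ifelse(tb < th$torpor_cutoff, "torpor",
         ifelse(tb > th$hyperthermia_cutoff, "hyperthermia", "euthermia"))
}

#' Classify every sample of a series
#'
#' Applies \code{\link{classify_sample}} with the route-corrected
#' thresholds for the series' implant route.
#'
#' @param series A \code{\link{tb_series}}.
#' @param th A \code{\link{thresholds}} object (pre-correction).
#' @return The series' records data frame with an added \code{state} column.
#' @export
classify_series <- function(series, th = thresholds()) {
  stopifnot(inherits(series, "tb_series"))
  eff <- effective_thresholds(th, series$meta$implant_route)
  out <- series$records
  out$state <- classify_sample(out$tb, eff)
  out
}

#' Assemble thermal bouts from a classified series
#'
#' Maximal runs of samples in the same state become bouts.  A data gap
#' longer than twice the nominal sampling interval closes the current bout
#' (preventing phantom multi-hour bouts across logger outages).  Bout
#' duration is (last - first sample time + one nominal interval), so a
#' single-sample bout lasts one interval.  Torpor bouts are labelled
#' \code{"short"} (< 24 h by default) or \code{"multiday"}.
#'
#' @param series A \code{\link{tb_series}}.
#' @param th A \code{\link{thresholds}} object (pre-correction).
#' @return Data frame: state, start, end (POSIXct), duration_h, kind.
#' @export
assemble_bouts <- function(series, th = thresholds()) {
  cl <- classify_series(series, th)
  n <- nrow(cl)
  if (n == 0)
    return(data.frame(state = character(), start = as.POSIXct(character()),
                      end = as.POSIXct(character()), duration_h = numeric(),
                      kind = character()))
  iv <- series$nominal_interval_s
  tn <- as.numeric(cl$timestamp)
  gap_before <- c(FALSE, diff(tn) > 2 * iv)
  new_run <- c(TRUE, cl$state[-1] != cl$state[-n]) | gap_before
  run_id <- cumsum(new_run)
  start <- tapply(tn, run_id, min)
  end <- tapply(tn, run_id, max)
  state <- tapply(cl$state, run_id, `[`, 1)
  dur <- (end - start + iv) / 3600
  kind <- ifelse(state == "torpor",
                 ifelse(dur >= th$multiday_cutoff_h, "multiday", "short"),
                 NA_character_)
  data.frame(state = as.character(state),
             start = as.POSIXct(as.numeric(start), origin = "1970-01-01",
                                tz = "UTC"),
             end = as.POSIXct(as.numeric(end), origin = "1970-01-01",
                              tz = "UTC"),
             duration_h = as.numeric(dur), kind = kind,
             row.names = NULL)
}

#' Daily summaries of a Tb series
#'
#' Groups samples by calendar day (local midnight boundary; the nocturnal
#' active phase therefore splits across two days, as it does in any
#' per-calendar-day metric).  \code{hours_above} is the count of
#' hyperthermic samples times the nominal interval — the simplest
#' defensible estimator at hourly cadence, with a ~0.5 h/day quantisation
#' on daily totals — capped at 24 h.  Days with fewer than
#' \code{min_samples} records are flagged incomplete and should be excluded
#' from weekly means downstream.  Ambient covariates are joined from
#' \code{ta} when it covers the day.
#'
#' @param series A \code{\link{tb_series}}.
#' @param ta Optional \code{\link{ta_series}}.
#' @param th A \code{\link{thresholds}} object (pre-correction).
#' @param min_samples Minimum samples for a complete day.
#' @return Data frame: date, n_samples, max_tb, min_tb, mean_tb,
#'   hours_above, torpor_day, complete, mean_ta, min_ta.
#' @export
daily_summaries <- function(series, ta = NULL, th = thresholds(),
                            min_samples = 12L) {
  cl <- classify_series(series, th)
  iv <- series$nominal_interval_s
  date <- as.Date(cl$timestamp, tz = "UTC")
  sp <- split(seq_len(nrow(cl)), date)
  out <- do.call(rbind, lapply(names(sp), function(d) {
    i <- sp[[d]]
    data.frame(date = as.Date(d), n_samples = length(i),
               max_tb = max(cl$tb[i]), min_tb = min(cl$tb[i]),
               mean_tb = mean(cl$tb[i]),
               hours_above = min(sum(cl$state[i] == "hyperthermia") *
                                   iv / 3600, 24),
               torpor_day = any(cl$state[i] == "torpor"))
  }))
  out$complete <- out$n_samples >= min_samples
  if (!is.null(ta)) {
    td <- .ta_daily(ta)
    m <- match(out$date, td$date)
    out$mean_ta <- td$mean_ta[m]
    out$min_ta <- td$min_ta[m]
  } else {
    out$mean_ta <- NA_real_
    out$min_ta <- NA_real_
  }
  row.names(out) <- NULL
  out
}

#' Detect hibernation onset
#'
#' The onset of hibernation is the start date of the earliest multiday
#' torpor bout beginning on or after \code{search_from} (August 1 of the
#' bout year by default).  The fall window excludes the occasional multiday
#' summer-dormancy bout from being mistaken for hibernation entry.
#' Returns \code{NA} (a missing Date, not an error) when no qualifying
#' bout exists.
#'
#' @param bouts A bout table from \code{\link{assemble_bouts}}.
#' @param search_from A \code{Date}, or \code{NULL} for August 1 of the
#'   year of the first bout.
#' @return The onset \code{Date}, or \code{NA}.
#' @export
detect_hibernation_onset <- function(bouts, search_from = NULL) {
  if (nrow(bouts) == 0) return(as.Date(NA))
  if (is.null(search_from)) {
    yr <- format(min(bouts$start), "%Y")
    search_from <- as.Date(paste0(yr, "-08-01"))
  }
  cand <- bouts[bouts$state == "torpor" &
                  !is.na(bouts$kind) & bouts$kind == "multiday" &
                  as.Date(bouts$start, tz = "UTC") >= as.Date(search_from), ,
                drop = FALSE]
  if (nrow(cand) == 0) return(as.Date(NA))
  as.Date(min(cand$start), tz = "UTC")
}

#' Torpor days per week
#'
#' Counts days with at least one torpor sample among complete days in each
#' week.  Days on or after hibernation onset are dropped first, and weeks
#' at or after the onset week are excluded entirely (the partial onset week
#' would understate frequency).
#'
#' @param days A daily-summary table from \code{\link{daily_summaries}}.
#' @param onset Hibernation-onset \code{Date}, or \code{NA} to keep all
#'   weeks.
#' @param week_fn Week indexer applied to dates (default
#'   \code{\link{week_of_year}}).
#' @return Data frame: week, torpor_days, n_days.
#' @export
torpor_days_per_week <- function(days, onset = as.Date(NA),
                                 week_fn = week_of_year) {
  d <- days[days$complete, , drop = FALSE]
  if (!is.na(onset)) d <- d[d$date < as.Date(onset), , drop = FALSE]
  if (nrow(d) == 0)
    return(data.frame(week = integer(), torpor_days = integer(),
                      n_days = integer()))
  wk <- week_fn(d$date)
  out <- data.frame(week = as.integer(names(table(wk))),
                    torpor_days = as.integer(tapply(d$torpor_day, wk, sum)),
                    n_days = as.integer(table(wk)), row.names = NULL)
  if (!is.na(onset)) out <- out[out$week < week_fn(as.Date(onset)), ,
                                drop = FALSE]
  row.names(out) <- NULL
  out
}
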