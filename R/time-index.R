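#' Week-of-year index (fixed 7-day blocks)
#'
#' Weeks are fixed 7-day blocks anchored at January 1 (days 1-7 are week 1,
#' days 8-14 week 2, ...), not ISO weeks.  This convention makes week 35 the
#' last week of August in any year and is locale-independent.  The final
#' block (week 53) is short.
#'
#' @param date A \code{Date} vector.
#' @return Integer week index in 1..53.
#' @examples
#' week_of_year(as.Date("2013-01-01"))  # 1
#' week_of_year(as.Date("2013-08-27"))  # 35
#' @export
week_of_year <- function(date) {
  date <- as.Date(date)
  doy <- as.integer(format(date, "%j"))
  as.integer((doy - 1L) %/% 7L) + 1L
}

#' Weeks prior to hibernation onset
#'
#' Backward week index anchored at the hibernation-onset date: week 0 is the
#' 7 days ending at onset (onset itself and the 6 preceding days), week -1
#' the 7 days before that, and so on.
#'
#' @param date A \code{Date} vector, each element on or before \code{onset}.
#' @param onset Hibernation-onset \code{Date} (scalar).
#' @return Integer vector of non-positive week indices.
#' @examples
#' on <- as.Date("2013-09-20")
#' weeks_prior_to_hibernation(on - c(0, 7, 10), on)  # 0 -1 -1
#' @export
weeks_prior_to_hibernation <- function(date, onset) {
  date <- as.Date(date); onset <- as.Date(onset)
  stopifnot(length(onset) == 1L)
  d <- as.integer(onset - date)
  if (any(d < 0)) stop("date after hibernation onset")
  -(d %/% 7L)
}
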