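#' Detect the parturition step in daily mean Tb
#'
#' Parturition shows as an abrupt, sustained rise (~0.5 degrees C) in daily
#' mean Tb.  The detector works on torpor-free complete days only — a
#' single torpor day depresses the daily mean by tens of degrees and would
#' dominate any step statistic.  For each candidate day d in the search
#' window it computes the symmetric window contrast
#' \code{c(d) = mean(mean_tb over the k days after d) - mean(mean_tb over
#' the k days up to d)}.  Local maxima of the contrast with
#' \code{c >= min_step} whose sign is sustained over the following k days
#' become candidates; the reported date is d + 1 (the first elevated day),
#' the step is c(d), and the score is c(d) divided by the residual SD of
#' detrended daily means.  Candidates are returned in date order with the
#' rank by score attached; multiple candidates are supported (e.g. a lost
#' first litter followed by a second).
#'
#' @param days Daily-summary table from \code{\link{daily_summaries}}.
#' @param window Date range (length-2 Date) to search; default weeks 26-37
#'   of the data's year, covering late-June through mid-September births.
#' @param k Days on each side of the contrast window.
#' @param min_step Minimum contrast (degrees C) to call a candidate.
#' @return Data frame: date, step, score, rank (1 = top-ranked).
#' @export
detect_parturition <- function(days, window = NULL, k = 5L, min_step = 0.3) {
  d <- days[days$complete & !days$torpor_day, , drop = FALSE]
  d <- d[order(d$date), , drop = FALSE]
  empty <- data.frame(date = as.Date(character()), step = numeric(),
                      score = numeric(), rank = integer())
  if (nrow(d) < 2 * k + 2) return(empty)
  if (is.null(window)) {
    yr <- format(d$date[1], "%Y")
    window <- c(as.Date(paste0(yr, "-01-01")) + (26L - 1L) * 7L,
                as.Date(paste0(yr, "-01-01")) + 37L * 7L - 1L)
  }
  window <- as.Date(window)
  if (window[1] > max(d$date) || window[2] < min(d$date))
    stop("parturition search window lies outside the data span")

  dates <- d$date
  y <- d$mean_tb
  n <- length(y)
  ## contrast on torpor-free day index; gaps from removed torpor days are
  ## bridged by using the k nearest retained days on each side
  contrast <- rep(NA_real_, n)
  for (i in (k + 1):(n - k)) {
    contrast[i] <- mean(y[(i + 1):(i + k)]) - mean(y[(i - k + 1):i])
  }
  ## residual SD after removing a light running-median trend
  trend <- stats::runmed(y, k = min(2L * k + 1L, n - (1 - n %% 2)))
  sdr <- sd(y - trend)
  if (!is.finite(sdr) || sdr < 1e-8) sdr <- 1e-8

  in_win <- !is.na(contrast) & dates >= window[1] & dates <= window[2]
  cand_i <- integer()
  for (i in which(in_win)) {
    if (contrast[i] < min_step) next
    lo <- max(1, i - k); hi <- min(n, i + k)
    if (contrast[i] < max(contrast[lo:hi], na.rm = TRUE) - 1e-12) next
    ## persistence: the rise must be sustained — the mean contrast over
    ## the following k days stays positive (day-level checks are too
    ## brittle at realistic daily-mean noise)
    fut <- contrast[(i + 1):min(n, i + k)]
    if (!all(is.na(fut)) && mean(fut, na.rm = TRUE) <= 0) next
    cand_i <- c(cand_i, i)
  }
  if (!length(cand_i)) return(empty)
  out <- data.frame(date = dates[cand_i] + 1L,
                    step = contrast[cand_i],
                    score = contrast[cand_i] / sdr)
  out <- out[order(out$date), , drop = FALSE]
  out$rank <- rank(-out$score, ties.method = "first")
  row.names(out) <- NULL
  out
}

#' Lactation-window highest minimum Tb
#'
#' The maximum over torpor-free complete days in weeks 30-35 (the lactation
#' period) of the daily minimum Tb — a proxy for Tb at resting metabolic
#' rate.  Requires at least \code{min_days} qualifying days; returns
#' \code{NA} otherwise.
#'
#' @param days Daily-summary table.
#' @param weeks Week-of-year range of the lactation window.
#' @param min_days Minimum qualifying days.
#' @return Highest daily minimum Tb (degrees C), or \code{NA}.
#' @export
lactation_peak_min_tb <- function(days, weeks = c(30L, 35L), min_days = 7L) {
  d <- days[days$complete & !days$torpor_day, , drop = FALSE]
  wk <- week_of_year(d$date)
  d <- d[wk >= weeks[1] & wk <= weeks[2], , drop = FALSE]
  if (nrow(d) < min_days) return(NA_real_)
  max(d$min_tb)
}

#' Week of the gestation activity dip
#'
#' The week (of year) with the minimum weekly mean hours above the
#' hyperthermia threshold, over weeks 27-31 — late gestation, when
#' activity collapses.  Ties go to the earlier week.
#'
#' @param weekly Data frame with columns \code{week} and
#'   \code{hours_above} (weekly mean h/day).
#' @param weeks Range of weeks to scan.
#' @return The dip week index, or \code{NA} if any week in range is absent.
#' @export
gestation_dip_week <- function(weekly, weeks = c(27L, 31L)) {
  w <- weekly[weekly$week >= weeks[1] & weekly$week <= weeks[2], ,
              drop = FALSE]
  if (!all(weeks[1]:weeks[2] %in% w$week)) return(NA_integer_)
  w <- w[order(w$week), , drop = FALSE]
  w$week[which.min(w$hours_above)]
}
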