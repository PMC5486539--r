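#' Generate an annual ambient-temperature series
#'
#' Hourly Ta for one calendar year from a seasonal sinusoid (annual mean
#' ~9 degrees C, peak in late July), a diel sinusoid (~8 degrees C
#' peak-to-trough, warmest mid-afternoon) and AR(1) day-to-day weather
#' noise.  This is a plausible temperate-deciduous-forest (Vienna-woods
#' style) stand-in, not a reconstruction of any measured site climate.
#'
#' @param year Calendar year.
#' @param seed Integer seed; the same (year, seed) pair always yields a
#'   byte-identical series.
#' @return A \code{\link{ta_series}} with hourly records for the full year.
#' @export
generate_ta <- function(year, seed = 1L) {
  .with_seed(.animal_seed(seed, paste0("ta-", year)), {
    origin <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC")
    end <- as.POSIXct(sprintf("%d-12-31 23:00:00", year), tz = "UTC")
    ts <- seq(origin, end, by = 3600)
    doy <- as.numeric(difftime(ts, origin, units = "days"))
    hour <- (as.numeric(ts) / 3600) %% 24
    seasonal <- 9 + 10 * cos(2 * pi * (doy - 200) / 365.25)
    diel <- -4 * cos(2 * pi * (hour - 14) / 24)
    nd <- ceiling(length(ts) / 24) + 1
    w <- numeric(nd)
    w[1] <- rnorm(1, 0, 3)
    innov <- rnorm(nd - 1, 0, 3 * sqrt(1 - 0.7^2))
    for (i in 2:nd) w[i] <- 0.7 * w[i - 1] + innov[i - 1]
    weather <- w[floor(doy) + 1]
    ta <- seasonal + diel + weather + rnorm(length(ts), 0, 0.6)
    ta_series(data.frame(timestamp = ts, ta = round(ta, 2)))
  })
}

## per-calendar-day mean and minimum Ta
.ta_daily <- function(ta) {
  stopifnot(inherits(ta, "ta_series"))
  date <- as.Date(ta$records$timestamp, tz = "UTC")
  data.frame(date = as.Date(tapply(as.character(date), date, `[`, 1)),
             mean_ta = as.numeric(tapply(ta$records$ta, date, mean)),
             min_ta = as.numeric(tapply(ta$records$ta, date, min)),
             row.names = NULL)
}
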