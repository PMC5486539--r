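#' Animal metadata record
#'
#' One row of study metadata for an animal-year.  \code{mast} is a property
#' of the (site, year) combination: a mast year offers abundant beech seed
#' and is the only condition under which dormice reproduce.
#'
#' @param animal_id Character id.
#' @param sex "female" or "male".
#' @param age_class "yearling" or "adult".
#' @param site "field" (free-living) or "enclosure" (ad libitum fed).
#' @param implant_route "intraperitoneal" or "subcutaneous".
#' @param year Integer calendar year.
#' @param mast "mast" or "failure" (beech seed crop condition).
#' @return An object of class \code{"animal_meta"}.
#' @export
animal_meta <- function(animal_id, sex = c("female", "male"),
                        age_class = c("adult", "yearling"),
                        site = c("field", "enclosure"),
                        implant_route = c("intraperitoneal", "subcutaneous"),
                        year, mast = c("failure", "mast")) {
  structure(list(animal_id = as.character(animal_id),
                 sex = match.arg(sex),
                 age_class = match.arg(age_class),
                 site = match.arg(site),
                 implant_route = match.arg(implant_route),
                 year = as.integer(year),
                 mast = match.arg(mast)),
            class = "animal_meta")
}

#' Body-temperature series
#'
#' Container for one animal-year of logger records: an \code{animal_meta},
#' an ordered data frame of (timestamp, tb) records, and the nominal
#' sampling interval.  Construction validates the series: finite Tb within
#' the physically plausible 0-45 degrees C band, strictly increasing
#' timestamps, median inter-sample gap within 20 percent of the nominal
#' interval, and a span of at least 21 days (shorter records carry too
#' little of the active season to analyse).
#'
#' @param meta An \code{\link{animal_meta}}.
#' @param records Data frame with columns \code{timestamp} (POSIXct) and
#'   \code{tb} (degrees C).
#' @param nominal_interval_s Nominal sampling interval in seconds.
#' @param validate Set \code{FALSE} to skip invariant checks (internal use).
#' @return An object of class \code{"tb_series"}.
#' @export
tb_series <- function(meta, records, nominal_interval_s = 3850,
                      validate = TRUE) {
  stopifnot(inherits(meta, "animal_meta"),
            is.data.frame(records),
            all(c("timestamp", "tb") %in% names(records)))
  records <- records[, c("timestamp", "tb")]
  if (validate) {
    if (!all(is.finite(records$tb)))
      stop("non-finite tb in series ", meta$animal_id)
    if (any(records$tb < 0 | records$tb > 45))
      stop("tb outside plausible 0-45 C band in series ", meta$animal_id)
    dt <- diff(as.numeric(records$timestamp))
    if (any(dt <= 0))
      stop("timestamps not strictly increasing in series ", meta$animal_id)
    if (length(dt)) {
      m <- median(dt)
      if (abs(m - nominal_interval_s) > 0.2 * nominal_interval_s)
        stop("median sampling gap ", round(m), " s departs >20% from nominal ",
             nominal_interval_s, " s in series ", meta$animal_id)
    }
    span_d <- diff(range(as.numeric(records$timestamp))) / 86400
    if (span_d < 21)
      stop("series ", meta$animal_id, " spans only ", round(span_d, 1),
           " days (minimum 21)")
  }
  structure(list(meta = meta, records = records,
                 nominal_interval_s = nominal_interval_s),
            class = "tb_series")
}

#' @export
print.tb_series <- function(x, ...) {
  cat(sprintf("<tb_series> %s %d (%s, %s, %s): %d samples, %s .. %s\n",
              x$meta$animal_id, x$meta$year, x$meta$sex, x$meta$site,
              x$meta$mast, nrow(x$records),
              format(min(x$records$timestamp)),
              format(max(x$records$timestamp))))
  invisible(x)
}

.parse_stamp <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M", "%d.%m.%y %H:%M:%S",
                                   "%d.%m.%Y %H:%M:%S", "%d.%m.%y %H:%M"))
  out
}

#' Read an iButton-style logger CSV
#'
#' Reads a per-animal logger export: optional header lines to skip, then
#' rows of timestamp and temperature.  Timestamps may be ISO 8601
#' ("2013-06-01 13:00:00") or logger-style "01.06.13 13:00:00"; all are
#' treated as naive local time (logger clocks are free-running, no DST).
#' Rows with duplicated timestamps keep the first occurrence; rows failing
#' the plausibility bounds (non-finite or outside 0-45 degrees C) are
#' dropped, each with a warning giving the count.
#'
#' @param path CSV file path.
#' @param meta \code{\link{animal_meta}} for the series.
#' @param skip Number of header lines before the column header.
#' @param timestamp_col,tb_col Column names in the file.
#' @param nominal_interval_s Nominal sampling interval (seconds).
#' @return A validated \code{\link{tb_series}}.
#' @export
read_logger_csv <- function(path, meta, skip = 0,
                            timestamp_col = "timestamp", tb_col = "tb",
                            nominal_interval_s = 3850) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- tryCatch(read.csv(path, skip = skip, stringsAsFactors = FALSE),
                error = function(e) stop("unparseable logger file ", path,
                                         ": ", conditionMessage(e)))
  if (!all(c(timestamp_col, tb_col) %in% names(d)))
    stop("logger file ", path, " lacks columns ",
         timestamp_col, "/", tb_col)
  ts <- .parse_stamp(d[[timestamp_col]])
  if (anyNA(ts)) stop("unparseable timestamps in ", path)
  tb <- suppressWarnings(as.numeric(d[[tb_col]]))
  rec <- data.frame(timestamp = ts, tb = tb)
  rec <- rec[order(rec$timestamp), , drop = FALSE]
  dup <- duplicated(rec$timestamp)
  if (any(dup)) {
    warning(sum(dup), " duplicated timestamp(s) in ", path, "; keeping first")
    rec <- rec[!dup, , drop = FALSE]
  }
  bad <- !is.finite(rec$tb) | rec$tb < 0 | rec$tb > 45
  if (any(bad)) {
    warning(sum(bad), " row(s) with implausible tb dropped from ", path)
    rec <- rec[!bad, , drop = FALSE]
  }
  tb_series(meta, rec, nominal_interval_s = nominal_interval_s)
}

#' Write a Tb series to CSV (round-trip safe)
#'
#' @param series A \code{\link{tb_series}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tb_csv <- function(series, path) {
  stopifnot(inherits(series, "tb_series"))
  out <- data.frame(
    timestamp = format(series$records$timestamp, "%Y-%m-%d %H:%M:%S"),
    tb = series$records$tb)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Ambient-temperature series
#'
#' @param records Data frame with columns \code{timestamp} (POSIXct) and
#'   \code{ta} (degrees C), strictly increasing timestamps.
#' @return An object of class \code{"ta_series"}.
#' @export
ta_series <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("timestamp", "ta") %in% names(records)))
  if (any(diff(as.numeric(records$timestamp)) <= 0))
    stop("ta timestamps not strictly increasing")
  structure(list(records = records[, c("timestamp", "ta")]),
            class = "ta_series")
}

#' Read an ambient-temperature CSV (same dialect as logger files)
#'
#' @inheritParams read_logger_csv
#' @param ta_col Temperature column name.
#' @return A \code{\link{ta_series}}.
#' @export
read_ta_csv <- function(path, skip = 0, timestamp_col = "timestamp",
                        ta_col = "ta") {
  d <- read.csv(path, skip = skip, stringsAsFactors = FALSE)
  ts <- .parse_stamp(d[[timestamp_col]])
  rec <- data.frame(timestamp = ts, ta = as.numeric(d[[ta_col]]))
  rec <- rec[order(rec$timestamp), , drop = FALSE]
  rec <- rec[!duplicated(rec$timestamp), , drop = FALSE]
  ta_series(rec)
}

#' Read an animal-metadata table
#'
#' One CSV keyed by \code{animal_id} + \code{year} with columns sex,
#' age_class, site, implant_route and mast.  Checks that \code{mast} is
#' consistent within each (site, year): the seed crop is a property of the
#' site-year, not of individual animals.
#'
#' @param path CSV path.
#' @return A list of \code{\link{animal_meta}} objects.
#' @export
read_meta_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "sex", "age_class", "site", "implant_route",
            "year", "mast")
  if (!all(need %in% names(d)))
    stop("metadata table lacks columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  key <- paste(d$site, d$year)
  bad <- tapply(d$mast, key, function(m) length(unique(m)) > 1)
  if (any(bad))
    stop("inconsistent mast condition within site-year: ",
         paste(names(bad)[bad], collapse = ", "))
  lapply(seq_len(nrow(d)), function(i)
    animal_meta(d$animal_id[i], d$sex[i], d$age_class[i], d$site[i],
                d$implant_route[i], d$year[i], d$mast[i]))
}
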