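#' Classification thresholds
#'
#' Container for the temperature cutoffs that define the three thermal
#' states and the bout-duration split.  Defaults follow the standard
#' operational definitions for edible dormice: torpor below 32 degrees C,
#' slight hyperthermia above 40 degrees C, and a 24 h cutoff separating
#' short (active-season) torpor bouts from multiday (hibernation-type)
#' bouts.  \code{subcutaneous_offset} is the correction applied to the
#' activity threshold for subcutaneously implanted animals, whose recorded
#' maxima run about 2 degrees C below intraperitoneal core readings.
#'
#' @param torpor_cutoff Tb below this is torpor (degrees C).
#' @param hyperthermia_cutoff Tb above this is slight hyperthermia (degrees C).
#' @param subcutaneous_offset Reduction of the hyperthermia cutoff for
#'   subcutaneous implants (degrees C).
#' @param multiday_cutoff_h Torpor bouts at least this long (hours) are
#'   "multiday"; shorter ones are "short".
#' @return An object of class \code{"thresholds"}.
#' @examples
#' th <- thresholds()
#' effective_thresholds(th, "subcutaneous")$hyperthermia_cutoff  # 38
#' @export
thresholds <- function(torpor_cutoff = 32, hyperthermia_cutoff = 40,
                       subcutaneous_offset = 2, multiday_cutoff_h = 24) {
  stopifnot(is.numeric(torpor_cutoff), is.numeric(hyperthermia_cutoff),
            is.numeric(subcutaneous_offset), is.numeric(multiday_cutoff_h))
  if (!(torpor_cutoff < hyperthermia_cutoff))
    stop("torpor_cutoff must be below hyperthermia_cutoff")
  if (any(c(torpor_cutoff, hyperthermia_cutoff,
            subcutaneous_offset, multiday_cutoff_h) <= 0))
    stop("all threshold values must be positive")
  structure(list(torpor_cutoff = torpor_cutoff,
                 hyperthermia_cutoff = hyperthermia_cutoff,
                 subcutaneous_offset = subcutaneous_offset,
                 multiday_cutoff_h = multiday_cutoff_h),
            class = "thresholds")
}

#' Route-corrected thresholds
#'
#' Subcutaneous loggers read lower than intraperitoneal ones during the
#' active phase, so the hyperthermia (activity) cutoff is lowered by
#' \code{subcutaneous_offset} for subcutaneous implants.  The torpor cutoff
#' is left unchanged: only the activity threshold needs the correction.
#' The operation is idempotent for intraperitoneal implants and applies the
#' offset exactly once for subcutaneous ones (call it once, at ingest).
#'
#' @param th A \code{\link{thresholds}} object.
#' @param route \code{"intraperitoneal"} or \code{"subcutaneous"}.
#' @return A \code{thresholds} object with the cutoff corrected.
#' @export
effective_thresholds <- function(th, route = c("intraperitoneal", "subcutaneous")) {
  stopifnot(inherits(th, "thresholds"))
  route <- match.arg(route)
  if (route == "subcutaneous")
    th$hyperthermia_cutoff <- th$hyperthermia_cutoff - th$subcutaneous_offset
  th
}
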