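#' @keywords internal
"_PACKAGE"

## small shared helpers -------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fledgr <- function(msg, class, ...) {
  stop(structure(class = c(class, "fledgr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

warn_fledgr <- function(msg, class) {
  warning(structure(class = c(class, "fledgr_warning", "warning", "condition"),
                    list(message = msg, call = sys.call(-1))))
}

is_finite_num <- function(x) is.numeric(x) && all(is.finite(x))

## angles in degrees ----------------------------------------------------------

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Normalize angles into [0, 360)
#' @param deg numeric vector of angles in degrees.
#' @return angles wrapped into `[0, 360)`.
#' @export
norm_angle_deg <- function(deg) {
  out <- deg %% 360
  out[out == 360] <- 0
  out
}

## circular difference a - b wrapped into (-180, 180]
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

## time handling --------------------------------------------------------------

#' Parse ISO-8601 UTC timestamps
#' @param x character vector like `"2015-08-06T21:00:00Z"` or with a space.
#' @return POSIXct in UTC.
#' @export
parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(x, tz = "UTC"))
  x <- gsub("T", " ", x, fixed = TRUE)
  x <- sub("Z$", "", x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  if (anyNA(out)) stop_fledgr("unparseable timestamp(s)", "fledgr_invalid_input")
  out
}

#' Format POSIXct as ISO-8601 UTC
#' @param t POSIXct vector.
#' @return character vector `"....Z"`.
#' @export
format_utc <- function(t) {
  format(as.POSIXct(t, tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Civil-time UTC offset for the study region
#'
#' Italian civil time: UTC+2 under daylight saving, UTC+1 otherwise, with the
#' switch at the last Sunday of October (the study window, August-November,
#' straddles it). A fixed offset can be supplied instead for other regions.
#'
#' @param t POSIXct (UTC) vector.
#' @param fixed_offset_minutes optional fixed offset; overrides the DST rule.
#' @return integer minutes east of UTC.
#' @export
local_offset_minutes <- function(t, fixed_offset_minutes = NULL) {
  if (!is.null(fixed_offset_minutes)) {
    if (abs(fixed_offset_minutes) > 14 * 60)
      stop_fledgr("utc offset outside +/-14 h", "fledgr_invalid_input")
    return(rep(as.integer(fixed_offset_minutes), length(t)))
  }
  t <- as.POSIXct(t, tz = "UTC")
  yr <- as.integer(format(t, "%Y", tz = "UTC"))
  # last Sunday of October, 01:00 UTC (CET/CEST switch)
  switch_utc <- vapply(unique(yr), function(y) {
    d <- as.Date(sprintf("%d-10-31", y))
    d <- d - (as.integer(format(d, "%w")))        # back to Sunday
    as.numeric(as.POSIXct(paste(d, "01:00:00"), tz = "UTC"))
  }, numeric(1))
  names(switch_utc) <- unique(yr)
  sw <- unname(switch_utc[as.character(yr)])
  ifelse(as.numeric(t) < sw, 120L, 60L)
}

#' Shift UTC timestamps to local civil time
#' @inheritParams local_offset_minutes
#' @return POSIXct still carrying tz UTC but shifted by the offset; use only
#'   for calendar/clock arithmetic (hour-of-day, date).
#' @export
to_local <- function(t, fixed_offset_minutes = NULL) {
  as.POSIXct(t, tz = "UTC") + 60 * local_offset_minutes(t, fixed_offset_minutes)
}

## local clock hour (decimal) and local date of a UTC instant
local_clock_hour <- function(t, fixed_offset_minutes = NULL) {
  lt <- to_local(t, fixed_offset_minutes)
  as.numeric(format(lt, "%H", tz = "UTC")) +
    as.numeric(format(lt, "%M", tz = "UTC")) / 60 +
    as.numeric(format(lt, "%S", tz = "UTC")) / 3600
}

local_date <- function(t, fixed_offset_minutes = NULL) {
  as.Date(format(to_local(t, fixed_offset_minutes), "%Y-%m-%d", tz = "UTC"))
}

#' Day of year of the local civil date
#' @inheritParams local_offset_minutes
#' @return integer day of year (1 = 1st of January).
#' @export
day_of_year_local <- function(t, fixed_offset_minutes = NULL) {
  as.integer(format(local_date(t, fixed_offset_minutes), "%j"))
}

## deterministic sub-seeds: keep below 2^31 ------------------------------------
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
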