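## Geodesy and solar timing.
##
## Distances are great-circle (haversine) on a sphere of mean radius
## 6371.0088 km; at the scales involved (<= ~1000 km) this is within 0.5% of
## an ellipsoidal geodesic and exactly reproducible. Bearings are spherical
## initial bearings. Sunset/sunrise follow the standard NOAA solar geometry
## with zenith 90.833 deg (refraction + solar radius).

EARTH_RADIUS_KM <- 6371.0088

#' Construct a geographic point
#'
#' @param lat_deg latitude in decimal degrees, in `[-90, 90]`.
#' @param lon_deg longitude in decimal degrees; normalized into `[-180, 180)`.
#' @return a `geo_point` (named list with `lat_deg`, `lon_deg`).
#' @export
geo_point <- function(lat_deg, lon_deg) {
  if (!is_finite_num(lat_deg) || !is_finite_num(lon_deg))
    stop_fledgr("non-finite coordinates", "fledgr_invalid_input")
  if (any(lat_deg < -90 | lat_deg > 90))
    stop_fledgr("latitude outside [-90, 90]", "fledgr_invalid_input")
  lon <- ((lon_deg + 180) %% 360) - 180
  structure(list(lat_deg = as.numeric(lat_deg), lon_deg = as.numeric(lon)),
            class = "geo_point")
}

as_lonlat <- function(p) {
  if (inherits(p, "geo_point")) cbind(p$lon_deg, p$lat_deg)
  else cbind(p[["lon_deg"]], p[["lat_deg"]])
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on the mean-radius sphere (R = 6371.0088 km). Vectorized
#' over points.
#'
#' @param a,b `geo_point`s (or lists with `lat_deg`/`lon_deg`).
#' @return distance in km.
#' @export
great_circle_km <- function(a, b) {
  pa <- as_lonlat(a); pb <- as_lonlat(b)
  if (!all(is.finite(pa)) || !all(is.finite(pb)))
    stop_fledgr("non-finite coordinates", "fledgr_invalid_input")
  geosphere::distHaversine(pa, pb, r = EARTH_RADIUS_KM * 1000) / 1000
}

## vectorized core used by track code: lat/lon numeric vectors
gc_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Initial bearing between two points
#'
#' Spherical initial bearing, degrees clockwise from true north in `[0, 360)`.
#'
#' @inheritParams great_circle_km
#' @return bearing in degrees.
#' @export
initial_bearing_deg <- function(a, b) {
  pa <- as_lonlat(a); pb <- as_lonlat(b)
  same <- abs(pa[, 1] - pb[, 1]) < 1e-9 & abs(pa[, 2] - pb[, 2]) < 1e-9
  if (any(same))
    stop_fledgr("bearing undefined for coincident points", "fledgr_undefined_bearing")
  norm_angle_deg(geosphere::bearing(pa, pb))
}

bearing_deg <- function(lat1, lon1, lat2, lon2) {
  norm_angle_deg(geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2)))
}

## --- solar geometry (NOAA-style, Fourier-series form) ------------------------

## fractional year (radians) at solar noonish resolution
.solar_gamma <- function(doy, hour) 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)

## equation of time (minutes) and solar declination (radians)
.solar_eqtime <- function(g) {
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g)
            - 0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
}

.solar_decl <- function(g) {
  (0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g)
   - 0.006758 * cos(2 * g) + 0.000907 * sin(2 * g)
   - 0.002697 * cos(3 * g) + 0.00148 * sin(3 * g))
}

#' Sunrise and sunset for a date and place
#'
#' Standard NOAA-style solar geometry with sunset/sunrise at solar zenith
#' 90.833 degrees. Polar day/night are flagged, not raised.
#'
#' @param p a [geo_point()].
#' @param date a `Date` (the local calendar date of interest).
#' @param utc_offset_minutes offset of the local clock from UTC (used only to
#'   pick the right UTC day for the local date); must be within +/-14 h.
#' @return a `solar_events` list: `date`, `sunrise_utc`, `sunset_utc`
#'   (POSIXct or NA), `polar_flag` (`"normal"`, `"polar_day"`, `"polar_night"`).
#' @export
solar_events <- function(p, date, utc_offset_minutes = 0) {
  if (abs(utc_offset_minutes) > 14 * 60)
    stop_fledgr("utc offset outside +/-14 h", "fledgr_invalid_input")
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  if (yr < 1990 || yr > 2050)
    stop_fledgr("date outside supported era 1990-2050", "fledgr_invalid_input")
  doy <- as.integer(format(date, "%j"))
  g <- .solar_gamma(doy, 12)
  eqt <- .solar_eqtime(g)
  dec <- .solar_decl(g)
  latr <- deg2rad(p$lat_deg)
  zen <- deg2rad(90.833)
  cos_ha <- (cos(zen) - sin(latr) * sin(dec)) / (cos(latr) * cos(dec))
  day0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  if (cos_ha < -1) {
    return(structure(list(date = date, sunrise_utc = as.POSIXct(NA),
                          sunset_utc = as.POSIXct(NA), polar_flag = "polar_day"),
                     class = "solar_events"))
  }
  if (cos_ha > 1) {
    return(structure(list(date = date, sunrise_utc = as.POSIXct(NA),
                          sunset_utc = as.POSIXct(NA), polar_flag = "polar_night"),
                     class = "solar_events"))
  }
  ha <- rad2deg(acos(cos_ha))                    # half day-length, degrees
  sunrise_min <- 720 - 4 * (p$lon_deg + ha) - eqt  # minutes UTC on `date`
  sunset_min  <- 720 - 4 * (p$lon_deg - ha) - eqt
  structure(list(date = date,
                 sunrise_utc = day0 + 60 * sunrise_min,
                 sunset_utc = day0 + 60 * sunset_min,
                 polar_flag = "normal"),
            class = "solar_events")
}

#' Hours after local sunset
#'
#' Signed decimal hours relative to the sunset nearest in time: 0 at sunset,
#' positive after (so after-midnight instants are referenced to the previous
#' evening's sunset), negative before.
#'
#' @param t POSIXct (UTC) vector.
#' @param p a [geo_point()].
#' @param utc_offset_minutes optional fixed local offset (defaults to the
#'   study-region DST rule via [local_offset_minutes()]).
#' @return numeric hours.
#' @export
hours_after_sunset <- function(t, p, utc_offset_minutes = NULL) {
  t <- as.POSIXct(t, tz = "UTC")
  off <- local_offset_minutes(t, utc_offset_minutes)
  dates <- local_date(t, utc_offset_minutes)
  udates <- sort(unique(c(dates - 1, dates, dates + 1)))
  sunsets <- vapply(seq_along(udates), function(i) {
    ev <- solar_events(p, udates[i], utc_offset_minutes = if (is.null(utc_offset_minutes)) 0 else utc_offset_minutes)
    if (ev$polar_flag != "normal")
      stop_fledgr("hours_after_sunset undefined under polar day/night",
                  "fledgr_not_computable")
    as.numeric(ev$sunset_utc)
  }, numeric(1))
  vapply(seq_along(t), function(i) {
    dt <- (as.numeric(t[i]) - sunsets) / 3600
    dt[which.min(abs(dt))]
  }, numeric(1))
}
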