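## Gridded weather: storage, space-time interpolation to fixes, and wind
## decomposition into speed/direction and tailwind/crosswind support.

WEATHER_VARIABLES <- c("temperature", "precipitation", "rel_humidity",
                       "pressure", "wind_u", "wind_v",
                       "cloud_low", "cloud_medium", "cloud_high")

#' Construct a weather grid
#'
#' A dense regular space-time raster for one variable, indexed
#' `[time, lat, lon]`. Emulates reanalysis granularities: 0.25 deg / 1 h for
#' weather variables and 0.75 deg / 6 h for cloud cover.
#'
#' @param variable one of `temperature, precipitation, rel_humidity, pressure,
#'   wind_u, wind_v, cloud_low, cloud_medium, cloud_high`.
#' @param times strictly increasing POSIXct (UTC).
#' @param lats,lons strictly increasing coordinate vectors (degrees).
#' @param values numeric array `length(times) x length(lats) x length(lons)`,
#'   all finite.
#' @return a `weather_grid` object.
#' @export
weather_grid <- function(variable, times, lats, lons, values) {
  variable <- match.arg(variable, WEATHER_VARIABLES)
  times <- as.POSIXct(times, tz = "UTC")
  if (length(times) > 1 && any(diff(as.numeric(times)) <= 0))
    stop_fledgr("times must be strictly increasing", "fledgr_invalid_input")
  if (any(diff(lats) <= 0) || any(diff(lons) <= 0))
    stop_fledgr("lats/lons must be strictly increasing", "fledgr_invalid_input")
  values <- array(as.numeric(values),
                  dim = c(length(times), length(lats), length(lons)))
  if (!all(is.finite(values)))
    stop_fledgr("non-finite values in weather grid", "fledgr_invalid_input")
  structure(list(variable = variable, times = times,
                 lats = as.numeric(lats), lons = as.numeric(lons),
                 values = values,
                 spatial_res_deg = if (length(lats) > 1) diff(lats)[1] else NA_real_,
                 temporal_step_h = if (length(times) > 1)
                   diff(as.numeric(times))[1] / 3600 else NA_real_),
            class = "weather_grid")
}

#' @export
print.weather_grid <- function(x, ...) {
  cat(sprintf("<weather_grid> %s: %d times x %d lats x %d lons (%.2f deg, %g h)\n",
              x$variable, length(x$times), length(x$lats), length(x$lons),
              x$spatial_res_deg, x$temporal_step_h))
  invisible(x)
}

## locate x in ascending grid g; returns list(i, w) with
## value ~ (1-w)*g[i] + w*g[i+1]; errors outside hull
.bracket <- function(x, g, what) {
  eps <- 1e-9
  if (any(x < g[1] - eps | x > g[length(g)] + eps))
    stop_fledgr(sprintf("query outside grid hull (%s)", what),
                "fledgr_extrapolation")
  i <- findInterval(x, g, rightmost.closed = TRUE)
  i[i < 1] <- 1L
  i[i >= length(g)] <- length(g) - 1L
  if (length(g) == 1) return(list(i = rep(1L, length(x)), w = rep(0, length(x))))
  w <- (x - g[i]) / (g[i + 1] - g[i])
  w <- pmin(pmax(w, 0), 1)
  list(i = i, w = w)
}

#' Interpolate a weather grid at points and times
#'
#' Bilinear in latitude/longitude at the two bracketing time slices, then
#' linear in time. Queries outside the grid hull raise an extrapolation error
#' (no silent clamping). Vectorized over fixes.
#'
#' @param grid a [weather_grid()].
#' @param lat,lon query coordinates (degrees), recycled to a common length.
#' @param t query times (POSIXct UTC).
#' @return numeric vector of interpolated values.
#' @export
interpolate_at <- function(grid, lat, lon, t) {
  t <- as.POSIXct(t, tz = "UTC")
  n <- max(length(lat), length(lon), length(t))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  tn <- rep_len(as.numeric(t), n)
  bt <- .bracket(tn, as.numeric(grid$times), "time")
  by <- .bracket(lat, grid$lats, "lat")
  bx <- .bracket(lon, grid$lons, "lon")
  v <- grid$values
  d <- dim(v)
  idx <- function(ti, yi, xi) v[cbind(ti, yi, xi)]
  interp_slice <- function(ti) {
    v00 <- idx(ti, by$i,     bx$i)
    v01 <- idx(ti, by$i,     bx$i + (length(grid$lons) > 1))
    v10 <- idx(ti, by$i + (length(grid$lats) > 1), bx$i)
    v11 <- idx(ti, by$i + (length(grid$lats) > 1), bx$i + (length(grid$lons) > 1))
    (v00 * (1 - by$w) + v10 * by$w) * (1 - bx$w) +
      (v01 * (1 - by$w) + v11 * by$w) * bx$w
  }
  s0 <- interp_slice(bt$i)
  s1 <- interp_slice(bt$i + (length(grid$times) > 1))
  s0 * (1 - bt$w) + s1 * bt$w
}

#' Annotate fixes with all variables of a weather set
#'
#' @param weather named list of [weather_grid()]s (a "weather set").
#' @param lat,lon,t as in [interpolate_at()].
#' @return data.frame with one column per variable plus derived
#'   `wind_speed_ms` and `wind_dir_to_deg` when both wind components exist.
#' @export
annotate_weather <- function(weather, lat, lon, t) {
  out <- as.data.frame(lapply(weather, interpolate_at, lat = lat, lon = lon, t = t))
  names(out) <- names(weather)
  if (all(c("wind_u", "wind_v") %in% names(out))) {
    wd <- wind_speed_dir(out$wind_u, out$wind_v)
    out$wind_speed_ms <- wd$speed
    out$wind_dir_to_deg <- wd$dir_to
  }
  out
}

#' Wind speed and blowing-toward direction from U/V components
#'
#' @param u eastward component (m/s).
#' @param v northward component (m/s).
#' @return list with `speed` (m/s) and `dir_to` (degrees clockwise from north,
#'   the bearing the wind blows TOWARD; `NA` for calm air).
#' @export
wind_speed_dir <- function(u, v) {
  if (!is_finite_num(u) || !is_finite_num(v))
    stop_fledgr("non-finite wind components", "fledgr_invalid_input")
  speed <- sqrt(u^2 + v^2)
  dir_to <- norm_angle_deg(rad2deg(atan2(u, v)))
  dir_to[speed == 0] <- NA_real_
  list(speed = speed, dir_to = dir_to)
}

#' Tailwind component along a flight direction
#'
#' `3.6 * v * cos(delta)` where `delta` is the angular deviation between the
#' flight direction and the blowing-toward wind direction: positive values are
#' tailwinds, negative headwinds. Result in km/h.
#'
#' @param wind_speed_ms wind speed, m/s (non-negative).
#' @param wind_dir_to_deg blowing-toward wind bearing, degrees.
#' @param flight_dir_deg flight bearing, degrees.
#' @return signed tailwind in km/h.
#' @export
tailwind_kmh <- function(wind_speed_ms, wind_dir_to_deg, flight_dir_deg) {
  if (any(wind_speed_ms < 0))
    stop_fledgr("negative wind speed", "fledgr_invalid_input")
  3.6 * wind_speed_ms * cos(deg2rad(circ_diff_deg(flight_dir_deg, wind_dir_to_deg)))
}

#' Crosswind component perpendicular to a flight direction
#'
#' `|3.6 * v * sin(delta)|`: the strength of the wind blowing perpendicular to
#' the movement, regardless of side. Result in km/h, non-negative.
#'
#' @inheritParams tailwind_kmh
#' @return crosswind in km/h (>= 0).
#' @export
crosswind_kmh <- function(wind_speed_ms, wind_dir_to_deg, flight_dir_deg) {
  if (any(wind_speed_ms < 0))
    stop_fledgr("negative wind speed", "fledgr_invalid_input")
  abs(3.6 * wind_speed_ms * sin(deg2rad(circ_diff_deg(flight_dir_deg, wind_dir_to_deg))))
}

## --- long-format CSV I/O ------------------------------------------------------

#' Write a weather set as long-format CSV
#'
#' Columns `variable,time_iso8601,lat,lon,value`; values are printed with
#' enough digits for a lossless round-trip. Intended for desk-scale fixtures.
#'
#' @param weather named list of [weather_grid()]s.
#' @param path output file.
#' @export
write_weather_csv <- function(weather, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("variable,time_iso8601,lat,lon,value", con)
  for (g in weather) {
    nt <- length(g$times); ny <- length(g$lats); nx <- length(g$lons)
    tt <- format_utc(g$times)
    rows <- sprintf("%s,%s,%.17g,%.17g,%.17g",
                    g$variable,
                    tt[rep(seq_len(nt), times = ny * nx)],
                    g$lats[rep(rep(seq_len(ny), each = nt), times = nx)],
                    g$lons[rep(seq_len(nx), each = nt * ny)],
                    as.vector(g$values))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a weather set from long-format CSV
#'
#' @param path file written by [write_weather_csv()] (or hand-made with the
#'   same columns; full rectangular coverage per variable is required).
#' @return named list of [weather_grid()]s.
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character",
                                       "numeric", "numeric", "numeric"))
  out <- list()
  for (v in unique(df$variable)) {
    d <- df[df$variable == v, ]
    times <- sort(unique(parse_utc(d$time_iso8601)))
    lats <- sort(unique(d$lat)); lons <- sort(unique(d$lon))
    if (nrow(d) != length(times) * length(lats) * length(lons))
      stop_fledgr(sprintf("incomplete grid coverage for %s", v),
                  "fledgr_invalid_input")
    a <- array(NA_real_, c(length(times), length(lats), length(lons)))
    ti <- match(as.numeric(parse_utc(d$time_iso8601)), as.numeric(times))
    yi <- match(d$lat, lats); xi <- match(d$lon, lons)
    a[cbind(ti, yi, xi)] <- d$value
    out[[v]] <- weather_grid(v, times, lats, lons, a)
  }
  out
}
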