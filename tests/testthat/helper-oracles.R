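# Independent oracles and shared fixtures, built in code.

# --- independent solar oracle -------------------------------------------------
# NOAA solar-calculator spreadsheet formulation (Julian centuries, geometric
# mean longitude/anomaly, eccentricity, obliquity). Independent of the
# package's Fourier-series implementation.
oracle_sunset_utc <- function(lat_deg, lon_deg, date) {
  date <- as.Date(date)
  jd <- as.numeric(date) + 2440587.5   # midnight UTC
  jc <- (jd - 2451545) / 36525
  gml <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  gma <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  ceq <- sin(gma * pi / 180) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gma * pi / 180) * (0.019993 - 0.000101 * jc) +
    sin(3 * gma * pi / 180) * 0.000289
  stl <- gml + ceq
  sal <- stl - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * jc) * pi / 180)
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  oc <- moe + 0.00256 * cos((125.04 - 1934.136 * jc) * pi / 180)
  decl <- asin(sin(oc * pi / 180) * sin(sal * pi / 180)) * 180 / pi
  vary <- tan(oc / 2 * pi / 180)^2
  eqtime <- 4 * (vary * sin(2 * gml * pi / 180) -
                   2 * ecc * sin(gma * pi / 180) +
                   4 * ecc * vary * sin(gma * pi / 180) * cos(2 * gml * pi / 180) -
                   0.5 * vary^2 * sin(4 * gml * pi / 180) -
                   1.25 * ecc^2 * sin(2 * gma * pi / 180)) * 180 / pi
  ha <- acos(cos(90.833 * pi / 180) / (cos(lat_deg * pi / 180) *
                                         cos(decl * pi / 180)) -
               tan(lat_deg * pi / 180) * tan(decl * pi / 180)) * 180 / pi
  solar_noon_min <- 720 - 4 * lon_deg - eqtime
  sunset_min <- solar_noon_min + 4 * ha
  as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + 60 * sunset_min
}

# equation of time (minutes), same spreadsheet formulation
oracle_eqtime_min <- function(date) {
  jd <- as.numeric(as.Date(date)) + 2440587.5
  jc <- (jd - 2451545) / 36525
  gml <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  gma <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  oc <- moe + 0.00256 * cos((125.04 - 1934.136 * jc) * pi / 180)
  vary <- tan(oc / 2 * pi / 180)^2
  4 * (vary * sin(2 * gml * pi / 180) -
         2 * ecc * sin(gma * pi / 180) +
         4 * ecc * vary * sin(gma * pi / 180) * cos(2 * gml * pi / 180) -
         0.5 * vary^2 * sin(4 * gml * pi / 180) -
         1.25 * ecc^2 * sin(2 * gma * pi / 180)) * 180 / pi
}

# --- tiny analytic weather grids ---------------------------------------------
# field value = a + b*lat + c*lon + d*hours ; linear, so trilinear
# interpolation must recover it exactly at interior points
linear_grid <- function(variable = "temperature",
                        a = 10, b = 0.5, c = -0.25, d = 0.1,
                        t0 = parse_utc("2015-08-01T00:00:00Z"),
                        nt = 5, lats = seq(39, 41, 0.5), lons = seq(8, 10, 0.5),
                        step_h = 1) {
  times <- t0 + (seq_len(nt) - 1) * step_h * 3600
  hrs <- (as.numeric(times) - as.numeric(t0)) / 3600
  vals <- array(0, c(nt, length(lats), length(lons)))
  for (i in seq_len(nt))
    vals[i, , ] <- outer(a + b * lats, c * lons, `+`) + d * hrs[i]
  weather_grid(variable, times, lats, lons, vals)
}

constant_wind_set <- function(u, v, t0 = parse_utc("2015-08-01T00:00:00Z"),
                              nt = 49, lats = seq(38, 46, 1),
                              lons = seq(8, 17, 1)) {
  times <- t0 + (seq_len(nt) - 1) * 3600
  mk <- function(var, val) weather_grid(var, times, lats, lons,
    array(val, c(nt, length(lats), length(lons))))
  list(wind_u = mk("wind_u", u), wind_v = mk("wind_v", v),
       temperature = mk("temperature", 22), precipitation = mk("precipitation", 0),
       rel_humidity = mk("rel_humidity", 60), pressure = mk("pressure", 1013),
       cloud_low = mk("cloud_low", 0.2), cloud_medium = mk("cloud_medium", 0.3),
       cloud_high = mk("cloud_high", 0.1))
}

# straight synthetic track builder: departs colony at dep_t flying at
# speed_kmh toward bearing, then dwells at the end point
straight_track <- function(colony, bearing, total_km, speed_kmh = 60,
                           start = parse_utc("2015-08-01T00:00:00Z"),
                           dep_t = parse_utc("2015-08-10T19:00:00Z"),
                           end = parse_utc("2015-10-15T00:00:00Z"),
                           bird_id = "T1", fix_h = 2) {
  times <- seq(start, end, by = fix_h * 3600)
  lat <- numeric(length(times)); lon <- numeric(length(times))
  cum <- 0; state <- "colony"
  pos <- c(colony$lat_deg, colony$lon_deg)
  for (k in seq_along(times)) {
    if (state == "colony" && times[k] >= dep_t) state <- "flying"
    if (state == "flying" && cum < total_km) {
      step <- min(speed_kmh * fix_h, total_km - cum)
      p <- geosphere::destPoint(cbind(pos[2], pos[1]), bearing, step * 1000,
                                r = 6371008.8)
      pos <- c(p[1, 2], p[1, 1]); cum <- cum + step
      if (cum >= total_km) state <- "arrived"
    }
    lat[k] <- pos[1]; lon[k] <- pos[2]
  }
  data.frame(bird_id = bird_id, t_utc = times, lat = lat, lon = lon,
             stringsAsFactors = FALSE)
}

# --- cached shared datasets ---------------------------------------------------
.fledgr_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fledgr_test_cache))
    assign(name, force(expr), envir = .fledgr_test_cache)
  get(name, envir = .fledgr_test_cache)
}

# small three-colony scenario used across module tests (15 birds, ~2 months)
small_cfg <- function(seed = 11) {
  sim_config(
    seed = seed,
    window = list(track_start = "2015-08-01", track_end = "2015-11-01",
                  weather_start = "2015-08-01", weather_end = "2015-10-01",
                  depart_earliest = "2015-08-05", depart_latest = "2015-09-18"),
    colonies = list(
      molentargius = utils::modifyList(sim_config()$colonies$molentargius,
                                       list(n_birds = 6)),
      comacchio = utils::modifyList(sim_config()$colonies$comacchio,
                                    list(n_birds = 4, depart_offset_days = 5)),
      margherita = utils::modifyList(sim_config()$colonies$margherita,
                                     list(n_birds = 5, depart_offset_days = 10))),
    n_female = 5)
}

small_dataset <- function() cached("small_dataset", {
  cfg <- small_cfg()
  ds <- simulate_dataset(cfg)
  seg <- segment_all_tracks(ds$fixes, ds$birds, cfg$colonies,
                            as.Date("2015-11-01"))
  events <- attach_pre_departure(seg$events, ds$fixes)
  list(cfg = cfg, ds = ds, seg = seg, events = events)
})

# build a track from a phase plan: list(c("fly", hours, bearing, speed_kmh))
# or list(c("dwell", hours)) starting at the colony; fixes every fix_h hours
track_from_plan <- function(colony, plan, start = parse_utc("2015-08-01T12:00:00Z"),
                            bird_id = "P1", fix_h = 2) {
  lat <- colony$lat_deg; lon <- colony$lon_deg
  lats <- lat; lons <- lon; times <- start
  t <- start
  for (ph in plan) {
    n_steps <- ceiling(as.numeric(ph$hours) / fix_h)
    for (s in seq_len(n_steps)) {
      t <- t + fix_h * 3600
      if (ph$type == "fly") {
        p <- geosphere::destPoint(cbind(lon, lat), ph$bearing,
                                  ph$speed * fix_h * 1000, r = 6371008.8)
        lat <- p[1, 2]; lon <- p[1, 1]
      }
      lats <- c(lats, lat); lons <- c(lons, lon); times <- c(times, t)
    }
  }
  data.frame(bird_id = bird_id, t_utc = times, lat = lats, lon = lons,
             stringsAsFactors = FALSE)
}
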