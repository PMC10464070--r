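## Track segmentation: resident/migrant classification and migration events
## (departure, stopovers, arrival) from 2-h GPS fix streams.
##
## Rules: a bird is a migrant when it departs on a flight beyond a 100-km
## radius from the natal colony AND arrives at the non-breeding site before
## 1 November of the hatching year. Departure is the first in-flight location
## after leaving the colony; arrival is the first location, after a directed
## movement of more than 100 km/day, of a dwell held for at least 20 days
## (the non-breeding site); en-route dwells of at least 12 h are stopovers.
##
## Knobs the source rules leave open (surfaced, not hidden): what counts as
## "in flight" (segment speed to the next fix >= 20 km/h while moving away
## from the colony), the colony residence radius (5 km) and the dwell
## membership radius (15 km around the running centroid).

#' Default segmentation parameters
#'
#' @param migration_radius_km radius around the colony beyond which an
#'   excursion can qualify as migration (100 km).
#' @param colony_radius_km residence radius around the colony (5 km).
#' @param flight_speed_kmh minimum segment speed for an "in flight" fix
#'   (20 km/h).
#' @param dwell_radius_km membership radius of a dwell cluster (15 km).
#' @param stopover_min_h minimum dwell for a stopover (12 h).
#' @param nonbreeding_min_days minimum stay at the non-breeding site (20 d).
#' @param min_daily_km directed-movement threshold before an arrival
#'   (100 km/day over a sliding 24-h window).
#' @param max_dwell_gap_h fix gaps longer than this inside a candidate dwell
#'   void its duration certificate (12 h).
#' @return named list of parameters.
#' @export
segmentation_params <- function(migration_radius_km = 100,
                                colony_radius_km = 5,
                                flight_speed_kmh = 20,
                                dwell_radius_km = 15,
                                stopover_min_h = 12,
                                nonbreeding_min_days = 20,
                                min_daily_km = 100,
                                max_dwell_gap_h = 12) {
  as.list(environment())
}

check_fixes <- function(fixes) {
  need <- c("t_utc", "lat", "lon")
  if (!is.data.frame(fixes) || !all(need %in% names(fixes)) || nrow(fixes) < 2)
    stop_fledgr("fixes must be a data.frame with >= 2 rows and t_utc/lat/lon",
                "fledgr_invalid_input")
  if (any(diff(as.numeric(fixes$t_utc)) <= 0))
    stop_fledgr("fix timestamps must be strictly increasing",
                "fledgr_invalid_ordering")
  fixes
}

#' Per-segment kinematics between consecutive fixes
#'
#' @param fixes data.frame with `t_utc` (POSIXct UTC), `lat`, `lon`, ordered
#'   in time.
#' @param exclude_final drop the final segment (used for speed analyses, where
#'   the deceleration into arrival and the coarse 2-h sampling would bias the
#'   last segment).
#' @return data.frame with one row per segment: `from`, `to` (row indices),
#'   `t_from`, `dt_h`, `dist_km`, `speed_kmh`, `bearing_deg`, `cumulative_km`
#'   (distance travelled up to the segment start).
#' @export
segment_kinematics <- function(fixes, exclude_final = FALSE) {
  check_fixes(fixes)
  n <- nrow(fixes)
  i <- seq_len(n - 1)
  dt_h <- diff(as.numeric(fixes$t_utc)) / 3600
  if (any(dt_h <= 0))
    stop_fledgr("non-increasing timestamps", "fledgr_invalid_ordering")
  dist_km <- gc_km(fixes$lat[i], fixes$lon[i], fixes$lat[i + 1], fixes$lon[i + 1])
  brg <- rep(NA_real_, n - 1)
  mv <- dist_km > 1e-9
  if (any(mv))
    brg[mv] <- bearing_deg(fixes$lat[i][mv], fixes$lon[i][mv],
                           fixes$lat[i + 1][mv], fixes$lon[i + 1][mv])
  out <- data.frame(from = i, to = i + 1,
                    t_from = fixes$t_utc[i],
                    dt_h = dt_h, dist_km = dist_km,
                    speed_kmh = dist_km / dt_h,
                    bearing_deg = brg,
                    cumulative_km = c(0, cumsum(dist_km)[-(n - 1)]))
  if (exclude_final) out <- out[-nrow(out), , drop = FALSE]
  out
}

## distance of every fix from the colony
.colony_dist <- function(fixes, colony) {
  gc_km(fixes$lat, fixes$lon, colony$lat_deg, colony$lon_deg)
}

#' Detect the migration departure fix
#'
#' The departure is the first in-flight fix of the excursion that crosses the
#' 100-km radius: the first fix outside the colony residence radius whose
#' segment speed to the next fix is at least `flight_speed_kmh` while moving
#' away from the colony.
#'
#' @param fixes one bird's fixes (data.frame `t_utc`, `lat`, `lon`).
#' @param colony the natal colony, a [geo_point()].
#' @param params a [segmentation_params()] list.
#' @return the row index of the departure fix (attribute `"warning"` set when
#'   the track starts already beyond the migration radius).
#' @export
detect_departure <- function(fixes, colony, params = segmentation_params()) {
  check_fixes(fixes)
  d <- .colony_dist(fixes, colony)
  n <- nrow(fixes)
  if (d[1] > params$migration_radius_km) {
    warn_fledgr("track already beyond migration radius at first fix",
                "fledgr_data_quality")
    out <- 1L
    attr(out, "warning") <- "start_beyond_radius"
    return(out)
  }
  ## excursions: maximal runs of fixes outside the colony residence radius
  outside <- d > params$colony_radius_km
  r <- rle(outside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (max(d[i0:i1]) <= params$migration_radius_km) next  # foraging loop
    ## first in-flight fix of this excursion
    for (i in i0:min(i1, n - 1)) {
      dt_h <- (as.numeric(fixes$t_utc[i + 1]) - as.numeric(fixes$t_utc[i])) / 3600
      sp <- gc_km(fixes$lat[i], fixes$lon[i], fixes$lat[i + 1], fixes$lon[i + 1]) / dt_h
      if (sp >= params$flight_speed_kmh && d[i + 1] > d[i]) return(i)
    }
    return(i0)  # qualifying excursion but no fix passes the speed gate
  }
  stop_fledgr("no excursion beyond the migration radius", "fledgr_no_departure")
}

## dwell clustering: greedy runs of fixes within dwell_radius_km of the
## running centroid, starting at from_idx
.find_dwells <- function(fixes, from_idx, params) {
  n <- nrow(fixes)
  res <- list()
  i <- from_idx
  while (i <= n) {
    j <- i
    latc <- fixes$lat[i]; lonc <- fixes$lon[i]; m <- 1
    while (j + 1 <= n &&
           gc_km(fixes$lat[j + 1], fixes$lon[j + 1], latc, lonc) <=
             params$dwell_radius_km) {
      j <- j + 1
      m <- m + 1
      latc <- latc + (fixes$lat[j] - latc) / m
      lonc <- lonc + (fixes$lon[j] - lonc) / m
    }
    dwell_h <- (as.numeric(fixes$t_utc[j]) - as.numeric(fixes$t_utc[i])) / 3600
    gap_h <- if (j > i) max(diff(as.numeric(fixes$t_utc[i:j])) / 3600) else 0
    res[[length(res) + 1]] <- list(entry = i, exit = j, dwell_h = dwell_h,
                                   max_gap_h = gap_h,
                                   lat = latc, lon = lonc)
    i <- j + 1
  }
  res
}

## directed-movement rate into fix idx: the maximum displacement rate
## (km/day, displacement to idx over the elapsed span, capped at 24 h) over
## fixes within the 24 h before idx (never before the departure). A dwell
## qualifies as reached "after a > 100 km/day directed movement" when some
## window shows that rate, so en-route pauses shortly before arrival do not
## mask a fast final approach.
.approach_daily_km <- function(fixes, idx, dep_idx) {
  t_idx <- as.numeric(fixes$t_utc[idx])
  ks <- seq(dep_idx, max(dep_idx, idx - 1))
  ks <- ks[t_idx - as.numeric(fixes$t_utc[ks]) <= 24 * 3600]
  if (!length(ks)) return(Inf)  # dwell starts within one fix of departure
  span_h <- pmax((t_idx - as.numeric(fixes$t_utc[ks])) / 3600, 1e-6)
  disp <- gc_km(fixes$lat[ks], fixes$lon[ks], fixes$lat[idx], fixes$lon[idx])
  max(disp * 24 / pmin(span_h, 24))
}

#' Detect arrival and en-route stopovers
#'
#' Walks forward from the departure fix, clustering dwells. The first dwell
#' reached after a directed movement exceeding `min_daily_km` per day and held
#' for at least `nonbreeding_min_days` is the non-breeding site; its first fix
#' is the arrival. Earlier dwells of at least `stopover_min_h` are stopovers.
#' Dwells containing fix gaps longer than `max_dwell_gap_h` lose their
#' duration certificate (with a data-quality warning).
#'
#' @inheritParams detect_departure
#' @param departure_idx row index returned by [detect_departure()].
#' @return list with `arrival_idx` and `stopovers` (data.frame `entry_idx`,
#'   `exit_idx`, `dwell_h`, `lat`, `lon`).
#' @export
detect_arrival_and_stopovers <- function(fixes, departure_idx,
                                         params = segmentation_params()) {
  check_fixes(fixes)
  dwells <- .find_dwells(fixes, departure_idx, params)
  stopovers <- list()
  for (dw in dwells) {
    if (dw$dwell_h < params$stopover_min_h) next
    if (dw$max_gap_h > params$max_dwell_gap_h) {
      warn_fledgr(sprintf("fix gap of %.1f h voids dwell at fixes %d-%d",
                          dw$max_gap_h, dw$entry, dw$exit),
                  "fledgr_data_quality")
      next
    }
    if (.approach_daily_km(fixes, dw$entry, departure_idx) < params$min_daily_km)
      next
    if (dw$dwell_h >= params$nonbreeding_min_days * 24) {
      return(list(arrival_idx = dw$entry,
                  stopovers = .stopover_df(stopovers, fixes)))
    }
    stopovers[[length(stopovers) + 1]] <- dw
  }
  stop_fledgr("no dwell satisfying the non-breeding rule before data end",
              "fledgr_open_ended_event")
}

.stopover_df <- function(stopovers, fixes) {
  if (length(stopovers) == 0)
    return(data.frame(entry_idx = integer(0), exit_idx = integer(0),
                      dwell_h = numeric(0), lat = numeric(0), lon = numeric(0)))
  data.frame(entry_idx = as.integer(vapply(stopovers, `[[`, 1, "entry")),
             exit_idx = as.integer(vapply(stopovers, `[[`, 1, "exit")),
             dwell_h = vapply(stopovers, `[[`, 1, "dwell_h"),
             lat = vapply(stopovers, `[[`, 1, "lat"),
             lon = vapply(stopovers, `[[`, 1, "lon"))
}

#' Classify a track as migrant or resident
#'
#' Migrant iff the bird departs on an excursion beyond the migration radius
#' and the resulting event's arrival falls before the deadline (1 November of
#' the hatching year, local civil date); otherwise resident.
#'
#' @inheritParams detect_departure
#' @param deadline a `Date`; arrivals on/after it do not count as migration.
#' @param utc_offset_minutes optional fixed local offset for the deadline test.
#' @return `"migrant"` or `"resident"`.
#' @export
classify_strategy <- function(fixes, colony, deadline,
                              params = segmentation_params(),
                              utc_offset_minutes = NULL) {
  check_fixes(fixes)
  dep <- tryCatch(suppressWarnings(detect_departure(fixes, colony, params)),
                  fledgr_no_departure = function(e) NULL)
  if (is.null(dep)) return("resident")
  arr <- tryCatch(suppressWarnings(
    detect_arrival_and_stopovers(fixes, dep, params)),
    fledgr_open_ended_event = function(e) NULL)
  if (is.null(arr)) return("resident")
  arr_date <- local_date(fixes$t_utc[arr$arrival_idx], utc_offset_minutes)
  if (arr_date < as.Date(deadline)) "migrant" else "resident"
}

#' Build the migration event of a migrant track
#'
#' @inheritParams classify_strategy
#' @return a `migration_event`: departure/arrival fixes, in-flight fixes,
#'   stopovers, total distance, duration, mean/max speed, and the
#'   departure-to-arrival destination bearing.
#' @export
migration_event <- function(fixes, colony, params = segmentation_params()) {
  dep <- detect_departure(fixes, colony, params)
  arr <- detect_arrival_and_stopovers(fixes, dep, params)
  seg <- segment_kinematics(fixes[dep:arr$arrival_idx, , drop = FALSE])
  total_km <- sum(seg$dist_km)
  dur_h <- (as.numeric(fixes$t_utc[arr$arrival_idx]) -
              as.numeric(fixes$t_utc[dep])) / 3600
  structure(list(
    bird_id = if ("bird_id" %in% names(fixes)) fixes$bird_id[1] else NA_character_,
    departure_idx = dep,
    arrival_idx = arr$arrival_idx,
    departure_fix = fixes[dep, , drop = FALSE],
    arrival_fix = fixes[arr$arrival_idx, , drop = FALSE],
    in_flight = fixes[dep:arr$arrival_idx, , drop = FALSE],
    stopovers = arr$stopovers,
    segments = seg,
    total_distance_km = total_km,
    duration_h = dur_h,
    mean_speed_kmh = total_km / dur_h,
    max_speed_kmh = max(seg$speed_kmh),
    destination_bearing_deg = bearing_deg(
      fixes$lat[dep], fixes$lon[dep],
      fixes$lat[arr$arrival_idx], fixes$lon[arr$arrival_idx])
  ), class = "migration_event")
}

#' @export
print.migration_event <- function(x, ...) {
  cat(sprintf(
    "<migration_event> %s: %s -> %s | %.0f km in %.1f h (mean %.1f, max %.1f km/h), %d stopover(s)\n",
    x$bird_id %||% "?", format_utc(x$departure_fix$t_utc),
    format_utc(x$arrival_fix$t_utc), x$total_distance_km, x$duration_h,
    x$mean_speed_kmh, x$max_speed_kmh, nrow(x$stopovers)))
  invisible(x)
}

#' One-row summary of a migration event
#'
#' @param event a [migration_event()].
#' @param utc_offset_minutes optional fixed local offset for calendar fields.
#' @return data.frame: bird, departure date/time, arrival position, duration,
#'   distance, mean and max speed, number of stopovers.
#' @export
summarize_event <- function(event, utc_offset_minutes = NULL) {
  data.frame(
    bird_id = event$bird_id,
    departure_utc = format_utc(event$departure_fix$t_utc),
    departure_date_local = as.character(
      local_date(event$departure_fix$t_utc, utc_offset_minutes)),
    departure_doy = day_of_year_local(event$departure_fix$t_utc,
                                      utc_offset_minutes),
    arrival_utc = format_utc(event$arrival_fix$t_utc),
    arrival_lat = event$arrival_fix$lat,
    arrival_lon = event$arrival_fix$lon,
    duration_h = event$duration_h,
    total_distance_km = event$total_distance_km,
    mean_speed_kmh = event$mean_speed_kmh,
    max_speed_kmh = event$max_speed_kmh,
    destination_bearing_deg = event$destination_bearing_deg,
    n_stopovers = nrow(event$stopovers),
    stringsAsFactors = FALSE
  )
}

## --- Movebank-style fix I/O ---------------------------------------------------

#' Read Movebank-style GPS fixes
#'
#' Expects columns `individual-local-identifier`, `timestamp` (ISO 8601 UTC),
#' `location-lat`, `location-long`.
#'
#' @param path CSV file.
#' @return data.frame `bird_id`, `t_utc` (POSIXct UTC), `lat`, `lon`, sorted
#'   by bird and time.
#' @export
read_fixes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("individual-local-identifier", "timestamp",
            "location-lat", "location-long")
  if (!all(need %in% names(df)))
    stop_fledgr(paste("missing columns:",
                      paste(setdiff(need, names(df)), collapse = ", ")),
                "fledgr_invalid_input")
  out <- data.frame(bird_id = as.character(df[["individual-local-identifier"]]),
                    t_utc = parse_utc(df[["timestamp"]]),
                    lat = as.numeric(df[["location-lat"]]),
                    lon = as.numeric(df[["location-long"]]),
                    stringsAsFactors = FALSE)
  out[order(out$bird_id, out$t_utc), , drop = FALSE]
}

#' Write fixes in Movebank-style CSV
#'
#' @param fixes data.frame `bird_id`, `t_utc`, `lat`, `lon`.
#' @param path output CSV.
#' @export
write_fixes_csv <- function(fixes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("individual-local-identifier,timestamp,location-lat,location-long", con)
  writeLines(sprintf("%s,%s,%.17g,%.17g", fixes$bird_id,
                     format_utc(fixes$t_utc), fixes$lat, fixes$lon), con)
  invisible(path)
}
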