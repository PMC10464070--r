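## The five study analyses as dataset builders plus model invocations:
## case-control departure GLMM (with an optional tailwind x distance
## interaction), in-flight speed LMM, phenology LMs, migration-distance LM.
## Weather covariates for the departure decision are evaluated AT THE COLONY;
## the flight direction is the departure-to-arrival bearing for the departure
## and seasonal analyses and the consecutive-fix bearing for the speed model.

#' Segment one bird's fixes into a migration event (convenience)
#'
#' @param fixes all birds' fixes (`bird_id`, `t_utc`, `lat`, `lon`).
#' @param birds biometrics table with `bird_id`, `colony`.
#' @param colonies named list of colony descriptors with `lat`/`lon` (e.g.
#'   `sim_config()$colonies`).
#' @param deadline migration deadline (1 November of the hatch year).
#' @param params a [segmentation_params()].
#' @return list: `strategies` (data.frame `bird_id`, `strategy`) and `events`
#'   (named list of [migration_event()]s for migrants).
#' @export
segment_all_tracks <- function(fixes, birds, colonies, deadline,
                               params = segmentation_params()) {
  strategies <- list(); events <- list()
  for (i in seq_len(nrow(birds))) {
    bid <- birds$bird_id[i]
    fx <- fixes[fixes$bird_id == bid, , drop = FALSE]
    cc <- colonies[[birds$colony[i]]]
    colony_pt <- geo_point(cc$lat, cc$lon)
    strat <- classify_strategy(fx, colony_pt, deadline, params)
    strategies[[i]] <- data.frame(bird_id = bid, strategy = strat,
                                  stringsAsFactors = FALSE)
    if (strat == "migrant")
      events[[bid]] <- migration_event(fx, colony_pt, params)
  }
  list(strategies = do.call(rbind, strategies), events = events)
}

## weather covariate block at (lat, lon, t) with tailwind/crosswind for a
## given flight bearing
.weather_covariates <- function(weather, lat, lon, t, flight_bearing) {
  w <- annotate_weather(weather, lat, lon, t)
  tw <- ifelse(is.na(w$wind_dir_to_deg), 0,
               tailwind_kmh(w$wind_speed_ms, w$wind_dir_to_deg, flight_bearing))
  cw <- ifelse(is.na(w$wind_dir_to_deg), 0,
               crosswind_kmh(w$wind_speed_ms, w$wind_dir_to_deg, flight_bearing))
  data.frame(tailwind = tw, crosswind = cw,
             wind_speed = w$wind_speed_ms * 3.6,
             pressure = w$pressure, humidity = w$rel_humidity,
             cloud_low = w$cloud_low, cloud_medium = w$cloud_medium,
             cloud_high = w$cloud_high,
             temperature = w$temperature, rain = w$precipitation)
}

#' Build the case-control departure table
#'
#' Per migrant: label-0 rows for every fix in the nightly window
#' (16:00-02:00 local, both endpoints included) within the 72 h preceding the
#' departure fix, and one label-1 row at the departure fix time. All weather
#' is evaluated at the colony; tailwind/crosswind use the
#' departure-to-arrival bearing. Rows without weather coverage are dropped
#' and counted.
#'
#' @param events named list of [migration_event()]s (names = bird ids).
#' @param birds biometrics table (`bird_id`, `sex`, `colony`, `year`).
#' @param colonies named list with `lat`/`lon` per colony.
#' @param weather weather set.
#' @param utc_offset_minutes optional fixed local offset.
#' @return data.frame (one row per case/control) with attribute
#'   `"dropped_rows"`.
#' @export
build_departure_cases <- function(events, birds, colonies, weather,
                                  utc_offset_minutes = NULL) {
  rows <- list(); dropped <- 0L
  for (bid in names(events)) {
    ev <- events[[bid]]
    b <- birds[birds$bird_id == bid, ]
    cc <- colonies[[b$colony]]
    colony_pt <- geo_point(cc$lat, cc$lon)
    dep_t <- ev$departure_fix$t_utc
    route_brg <- ev$destination_bearing_deg
    fx <- ev$all_fixes %||% NULL
    ## control candidates: the bird's fixes in (dep - 72 h, dep)
    cand_t <- ev$pre_departure_times
    if (is.null(cand_t))
      stop_fledgr("events must carry pre_departure_times (see attach_pre_departure)",
                  "fledgr_invalid_input")
    clk <- local_clock_hour(cand_t, utc_offset_minutes)
    keep <- (clk >= 16 | clk <= 2) &
      as.numeric(dep_t) - as.numeric(cand_t) <= 72 * 3600 &
      as.numeric(cand_t) < as.numeric(dep_t)
    tt <- c(cand_t[keep], dep_t)
    lab <- c(rep(0L, sum(keep)), 1L)
    wc <- tryCatch(
      .weather_covariates(weather, colony_pt$lat_deg, colony_pt$lon_deg, tt,
                          route_brg),
      fledgr_extrapolation = function(e) NULL)
    if (is.null(wc)) {
      ## per-row coverage: drop uncovered rows, keep the rest
      ok <- vapply(seq_along(tt), function(i) {
        !inherits(tryCatch(
          .weather_covariates(weather, colony_pt$lat_deg, colony_pt$lon_deg,
                              tt[i], route_brg),
          fledgr_extrapolation = function(e) e), "fledgr_extrapolation")
      }, logical(1))
      dropped <- dropped + sum(!ok)
      if (!any(ok)) next
      tt <- tt[ok]; lab <- lab[ok]
      wc <- .weather_covariates(weather, colony_pt$lat_deg, colony_pt$lon_deg,
                                tt, route_brg)
    }
    rows[[bid]] <- cbind(
      data.frame(bird_id = bid,
                 t_utc = tt,
                 t_local = format(to_local(tt, utc_offset_minutes),
                                  "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                 label = lab,
                 hours_after_sunset = hours_after_sunset(tt, colony_pt,
                                                         utc_offset_minutes),
                 colony = b$colony, year = b$year, sex = b$sex,
                 distance_km = ev$total_distance_km,
                 stringsAsFactors = FALSE),
      wc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dropped_rows") <- dropped
  out
}

#' Attach pre-departure fix times to events
#'
#' The case-control builder needs the candidate (pre-departure) fix times of
#' each migrant; this pulls them from the full fix table.
#'
#' @param events named list of [migration_event()]s.
#' @param fixes full fix table.
#' @return the events, each with a `pre_departure_times` element.
#' @export
attach_pre_departure <- function(events, fixes) {
  for (bid in names(events)) {
    fx <- fixes[fixes$bird_id == bid, , drop = FALSE]
    dep_t <- events[[bid]]$departure_fix$t_utc
    events[[bid]]$pre_departure_times <-
      fx$t_utc[as.numeric(fx$t_utc) < as.numeric(dep_t)]
  }
  events
}

## model formula pieces: only factors with > 1 level enter
.factor_terms <- function(data, vars) {
  vars[vapply(vars, function(v) length(unique(data[[v]])) > 1, logical(1))]
}

WEATHER_TERMS <- c("crosswind", "wind_speed", "tailwind", "pressure",
                   "humidity", "cloud_medium", "cloud_high", "cloud_low",
                   "temperature", "rain")

#' Departure-probability GLMM
#'
#' Binomial (logit) GLMM of the case-control label on the colony weather,
#' hours after sunset (linear + quadratic), sex, colony and year, with a
#' random intercept per bird. Continuous predictors are VIF-screened
#' (threshold 3) and standardized. Reference levels: colony Comacchio, first
#' year.
#'
#' @param cases table from [build_departure_cases()].
#' @param vif_threshold collinearity screen threshold.
#' @param interaction_distance add the tailwind x migration-distance
#'   interaction (the long-journey wind-selectivity test).
#' @param semipartial compute semi-partial R2 per predictor.
#' @return a [fledgr_fit].
#' @export
fit_departure_model <- function(cases, vif_threshold = 3,
                                interaction_distance = FALSE,
                                semipartial = FALSE) {
  d <- cases
  if (length(unique(d$bird_id)) < 2)
    warn_fledgr("single bird: random intercept at boundary",
                "fledgr_boundary")
  if ("comacchio" %in% d$colony)
    d$colony <- stats::relevel(factor(d$colony), ref = "comacchio")
  cont <- intersect(WEATHER_TERMS, names(d))
  cont <- cont[vapply(cont, function(v) stats::sd(d[[v]]) > 0, logical(1))]
  vs <- if (length(cont) >= 2)
    vif_screen(d[cont], threshold = vif_threshold) else list(retained = cont)
  fterms <- .factor_terms(d, c("sex", "colony", "year"))
  rhs <- c(vs$retained, fterms,
           "hours_after_sunset", "I(hours_after_sunset^2)")
  if (interaction_distance) rhs <- c(rhs, "distance_km", "tailwind:distance_km")
  f <- stats::as.formula(paste("label ~", paste(rhs, collapse = " + "),
                               "+ (1 | bird_id)"))
  fit <- fit_glmm_binomial(f, d, standardize = TRUE, semipartial = semipartial)
  fit$vif <- vs
  fit
}

#' @rdname fit_departure_model
#' @export
fit_departure_distance_interaction <- function(cases, vif_threshold = 3,
                                               semipartial = FALSE) {
  if (stats::sd(cases$distance_km) == 0)
    warn_fledgr("migration distance constant across birds: interaction aliased",
                "fledgr_aliased")
  fit_departure_model(cases, vif_threshold = vif_threshold,
                      interaction_distance = TRUE, semipartial = semipartial)
}

#' Build the per-segment speed table
#'
#' Consecutive-fix speeds over each migrant's flight (final segment excluded),
#' annotated with weather at the segment start using the segment bearing for
#' tailwind/crosswind, plus cumulative distance travelled. Segments inside
#' stopovers (speed below `min_flight_kmh`) are dropped.
#'
#' @param events named list of [migration_event()]s.
#' @param birds biometrics table.
#' @param weather weather set.
#' @param min_flight_kmh drop slower-than-flight segments (stopover dwell).
#' @return data.frame, one row per in-flight segment.
#' @export
build_speed_table <- function(events, birds, weather, min_flight_kmh = 20) {
  rows <- list()
  for (bid in names(events)) {
    ev <- events[[bid]]
    b <- birds[birds$bird_id == bid, ]
    seg <- segment_kinematics(ev$in_flight, exclude_final = TRUE)
    seg <- seg[seg$speed_kmh >= min_flight_kmh & !is.na(seg$bearing_deg), ,
               drop = FALSE]
    if (!nrow(seg)) next
    lat0 <- ev$in_flight$lat[seg$from]; lon0 <- ev$in_flight$lon[seg$from]
    wc <- .weather_covariates(weather, lat0, lon0, seg$t_from, seg$bearing_deg)
    rows[[bid]] <- cbind(
      data.frame(bird_id = bid, sex = b$sex, colony = b$colony, year = b$year,
                 t_utc = seg$t_from, speed_kmh = seg$speed_kmh,
                 cumulative_km = seg$cumulative_km,
                 stringsAsFactors = FALSE),
      wc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' In-flight speed LMM
#'
#' Gaussian LMM of consecutive-fix speed on weather (with quadratic humidity),
#' sex, colony, year and cumulative distance (linear + quadratic), random
#' intercept per bird. `sex_tailwind_interaction` fits the focused
#' sex x tailwind variant instead.
#'
#' @param speed_table from [build_speed_table()].
#' @param sex_tailwind_interaction add `sex:tailwind`.
#' @param vif_threshold collinearity screen threshold.
#' @param semipartial compute semi-partial R2 per predictor.
#' @return a [fledgr_fit].
#' @export
fit_speed_model <- function(speed_table, sex_tailwind_interaction = FALSE,
                            vif_threshold = 3, semipartial = FALSE) {
  d <- speed_table
  if ("comacchio" %in% d$colony)
    d$colony <- stats::relevel(factor(d$colony), ref = "comacchio")
  cont <- intersect(setdiff(WEATHER_TERMS, "wind_speed"), names(d))
  cont <- cont[vapply(cont, function(v) stats::sd(d[[v]]) > 0, logical(1))]
  vs <- if (length(cont) >= 2)
    vif_screen(d[cont], threshold = vif_threshold) else list(retained = cont)
  fterms <- .factor_terms(d, c("sex", "colony", "year"))
  rhs <- c(fterms, vs$retained,
           if ("humidity" %in% vs$retained) "I(humidity^2)",
           "cumulative_km", "I(cumulative_km^2)")
  if (sex_tailwind_interaction) rhs <- c(rhs, "sex:tailwind")
  f <- stats::as.formula(paste("speed_kmh ~", paste(rhs, collapse = " + "),
                               "+ (1 | bird_id)"))
  fit <- fit_lmm(f, d, standardize = TRUE, semipartial = semipartial)
  fit$vif <- vs
  fit
}

#' Fitted speed-vs-distance vertex
#'
#' Location (km) of the maximum of the fitted quadratic cumulative-distance
#' profile, back-transformed from the standardized scale:
#' `center - scale * b1 / (2 b2)`.
#'
#' @param fit a speed-model [fledgr_fit].
#' @return vertex in km.
#' @export
speed_vertex_km <- function(fit) {
  b <- coef(fit)
  b1 <- b[["cumulative_km"]]; b2 <- b[["I(cumulative_km^2)"]]
  ctr <- fit$scaling$center[["cumulative_km"]]
  scl <- fit$scaling$scale[["cumulative_km"]]
  ctr - scl * b1 / (2 * b2)
}

#' Phenology linear models
#'
#' Departure day of year (local civil date) as a function of sex, colony,
#' their interaction, year and total migration distance; each biometric (and
#' the SMI) is added in a separate model to avoid collinearity.
#'
#' @param event_summaries data.frame from [summarize_event()] rows.
#' @param birds biometrics table (with `smi_g`).
#' @return named list of [fledgr_fit]s: `base`, `tarsus`, `mass`, `wing`,
#'   `smi`.
#' @export
fit_phenology_models <- function(event_summaries, birds) {
  d <- merge(event_summaries, birds, by = "bird_id")
  if ("comacchio" %in% d$colony)
    d$colony <- stats::relevel(factor(d$colony), ref = "comacchio")
  fterms <- .factor_terms(d, c("sex", "colony", "year"))
  base_rhs <- c(if (all(c("sex", "colony") %in% fterms)) "sex * colony"
                else fterms[fterms %in% c("sex", "colony")],
                fterms[fterms == "year"], "total_distance_km")
  fits <- list(base = fit_lm(stats::as.formula(
    paste("departure_doy ~", paste(base_rhs, collapse = " + "))), d))
  for (v in c(tarsus = "tarsus_mm", mass = "mass_g", wing = "wing_mm",
              smi = "smi_g")) {
    nm <- names(which(c(tarsus = "tarsus_mm", mass = "mass_g",
                        wing = "wing_mm", smi = "smi_g") == v))
    fits[[nm]] <- fit_lm(stats::as.formula(
      paste("departure_doy ~", paste(c(base_rhs, v), collapse = " + "))), d)
  }
  fits
}

#' Migration-distance linear model
#'
#' Total migration distance per bird against weather averaged (unweighted)
#' over the annotated in-flight fixes of the route, with sex, colony and
#' departure date as covariates. Events with fewer than 2 annotated fixes
#' are dropped and counted.
#'
#' @param events named list of [migration_event()]s.
#' @param event_summaries matching [summarize_event()] rows.
#' @param birds biometrics table.
#' @param weather weather set.
#' @return a [fledgr_fit] with attribute `"dropped_events"`.
#' @export
fit_distance_model <- function(events, event_summaries, birds, weather) {
  rows <- list(); dropped <- 0L
  for (bid in names(events)) {
    ev <- events[[bid]]
    fx <- ev$in_flight
    wc <- tryCatch(
      .weather_covariates(weather, fx$lat, fx$lon,
                          pmin(fx$t_utc, max(weather$wind_u$times)),
                          ev$destination_bearing_deg),
      fledgr_extrapolation = function(e) NULL)
    if (is.null(wc) || nrow(wc) < 2) { dropped <- dropped + 1L; next }
    rows[[bid]] <- data.frame(bird_id = bid, t(colMeans(wc)),
                              stringsAsFactors = FALSE)
  }
  ra <- do.call(rbind, rows)
  d <- merge(merge(event_summaries, ra, by = "bird_id"), birds, by = "bird_id")
  if (stats::sd(d$total_distance_km) == 0)
    stop_fledgr("zero-variance response (all distances equal)",
                "fledgr_invalid_input")
  if ("comacchio" %in% d$colony)
    d$colony <- stats::relevel(factor(d$colony), ref = "comacchio")
  fterms <- .factor_terms(d, c("sex", "colony"))
  cont <- intersect(setdiff(WEATHER_TERMS, "wind_speed"), names(d))
  cont <- cont[vapply(cont, function(v) stats::sd(d[[v]]) > 0, logical(1))]
  vs <- if (length(cont) >= 2) vif_screen(d[cont], threshold = 3)
        else list(retained = cont)
  f <- stats::as.formula(paste("total_distance_km ~",
                               paste(c(fterms, "departure_doy", vs$retained),
                                     collapse = " + ")))
  fit <- fit_lm(f, d)
  fit$vif <- vs
  attr(fit, "dropped_events") <- dropped
  fit
}
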