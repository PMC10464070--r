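# A hand-built one-migrant scenario with constant wind and a clean fix
# schedule, used to pin down the case-control builder's window arithmetic.
one_migrant_setup <- function(dep_local_hour = 22) {
  colony <- geo_point(44.6053, 12.1747)
  # fixes on even local hours (UTC+2 in August): UTC even hours work since
  # the offset is +120 min
  start <- parse_utc("2015-08-01T00:00:00Z")
  dep_t <- parse_utc(sprintf("2015-08-10T%02d:00:00Z", dep_local_hour - 2))
  tr <- straight_track(colony, bearing = 30, total_km = 180, speed_kmh = 60,
                       start = start, dep_t = dep_t, bird_id = "B1")
  birds <- data.frame(bird_id = "B1", sex = "F", colony = "c1", year = 2015,
                      stringsAsFactors = FALSE)
  colonies <- list(c1 = list(lat = colony$lat_deg, lon = colony$lon_deg))
  w <- constant_wind_set(u = 3, v = 4,
                         nt = 24 * 20, lats = seq(43, 47, 0.5),
                         lons = seq(11, 15, 0.5))
  ev <- migration_event(tr, colony)
  events <- attach_pre_departure(stats::setNames(list(ev), "B1"), tr)
  list(events = events, birds = birds, colonies = colonies, weather = w,
       colony = colony)
}

test_that("case-control builder enumerates 18 nightly control rows over 3 days", {
  s <- one_migrant_setup(dep_local_hour = 22)
  cc <- build_departure_cases(s$events, s$birds, s$colonies, s$weather)
  expect_equal(sum(cc$label == 0), 18)  # 6 eligible clock hours x 3 days
  expect_equal(sum(cc$label == 1), 1)
  # the label-1 row carries the colony weather at the departure time exactly
  dep_row <- cc[cc$label == 1, ]
  u <- interpolate_at(s$weather$wind_u, s$colony$lat_deg, s$colony$lon_deg,
                      dep_row$t_utc)
  v <- interpolate_at(s$weather$wind_v, s$colony$lat_deg, s$colony$lon_deg,
                      dep_row$t_utc)
  wd <- wind_speed_dir(u, v)
  expect_equal(dep_row$tailwind,
               tailwind_kmh(wd$speed, wd$dir_to,
                            s$events$B1$destination_bearing_deg),
               tolerance = 1e-9)
  # deterministic and idempotent
  cc2 <- build_departure_cases(s$events, s$birds, s$colonies, s$weather)
  expect_identical(cc, cc2)
})

test_that("a departure at 02:00 local keeps its label-1 row at the window edge", {
  s <- one_migrant_setup(dep_local_hour = 2)
  cc <- build_departure_cases(s$events, s$birds, s$colonies, s$weather)
  expect_equal(sum(cc$label == 1), 1)
  expect_equal(local_offset_minutes(cc$t_utc[cc$label == 1]), 120)
})

test_that("departure GLMM recovers the generative hazard structure", {
  set.seed(40)
  # person-period hazard simulation on the standardized covariate scale
  truth <- c(`(Intercept)` = -4.97, tailwind = 1.41,
             hours_after_sunset = 4.37, `I(hours_after_sunset^2)` = -2.52)
  h_std <- (c(-3.5, -1.5, 0.5, 2.5, 4.5, 6.5) - 1.5) / 2.5
  sim_cases <- function(n_birds, nights = 4, shuffle_tailwind = FALSE) {
    rows <- lapply(seq_len(n_birds), function(i) {
      u <- rnorm(1, 0, 0.8)
      tw <- rnorm(nights * 6)
      hs <- rep(h_std, nights)
      p <- plogis(truth[1] + truth[2] * tw + truth[3] * hs + truth[4] * hs^2 + u)
      y <- rbinom(length(p), 1, p)
      upto <- if (any(y == 1)) which(y == 1)[1] else length(y)
      data.frame(bird_id = i, label = y[seq_len(upto)],
                 tailwind = tw[seq_len(upto)],
                 hours_after_sunset = hs[seq_len(upto)],
                 crosswind = rnorm(upto),   # no effect in truth
                 sex = "F", colony = "c", year = 2015,
                 distance_km = runif(1, 100, 800))
    })
    d <- do.call(rbind, rows)
    if (shuffle_tailwind) d$tailwind <- sample(d$tailwind)
    d
  }
  d <- sim_cases(150)
  f <- suppressMessages(fit_departure_model(d))
  ct <- f$coef_table
  expect_lt(ct$p[ct$term == "tailwind"], 0.05)
  expect_lt(ct$p[ct$term == "hours_after_sunset"], 0.05)
  i <- ct$term == "crosswind"
  expect_true(ct$ci_lo[i] <= 0 && 0 <= ct$ci_hi[i])
  # permutation null: shuffled tailwind shows no effect
  d0 <- sim_cases(150, shuffle_tailwind = TRUE)
  f0 <- suppressMessages(fit_departure_model(d0))
  ct0 <- f0$coef_table
  j <- ct0$term == "tailwind"
  expect_true(ct0$ci_lo[j] <= 0 && 0 <= ct0$ci_hi[j])
})

test_that("tailwind x distance interaction recovers its generative sign", {
  set.seed(41)
  h_std <- (c(-3.5, -1.5, 0.5, 2.5, 4.5, 6.5) - 1.5) / 2.5
  hits <- 0; reps <- 10
  for (r in seq_len(reps)) {
    rows <- lapply(1:120, function(i) {
      u <- rnorm(1, 0, 0.5)
      dist_z <- rnorm(1)
      tw <- rnorm(24)
      hs <- rep(h_std, 4)
      p <- plogis(-4.5 + 1.2 * tw + 4.37 * hs - 2.52 * hs^2 +
                    0.8 * tw * dist_z + u)
      y <- rbinom(24, 1, p)
      upto <- if (any(y == 1)) which(y == 1)[1] else 24
      data.frame(bird_id = i, label = y[seq_len(upto)],
                 tailwind = tw[seq_len(upto)],
                 hours_after_sunset = hs[seq_len(upto)],
                 sex = "F", colony = "c", year = 2015, distance_km = dist_z)
    })
    d <- do.call(rbind, rows)
    f <- suppressMessages(fit_departure_distance_interaction(d))
    ct <- f$coef_table
    est <- ct$estimate[grepl("tailwind:distance_km", ct$term)]
    if (length(est) == 1 && est > 0) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("constant distance leaves the interaction aliased with a warning", {
  set.seed(42)
  d <- data.frame(bird_id = rep(1:10, each = 10),
                  label = rbinom(100, 1, 0.2),
                  tailwind = rnorm(100),
                  hours_after_sunset = rnorm(100),
                  sex = "F", colony = "c", year = 2015, distance_km = 400)
  expect_warning(suppressMessages(fit_departure_distance_interaction(d)),
                 class = "fledgr_aliased")
})

test_that("speed model recovers the concave distance profile and sex contrast", {
  set.seed(43)
  mu_d <- 306.7; sd_d <- 200
  sim_speed <- function(n_birds = 30, nobs = 30, b_tw_f = 8.52, b_tw_m = 8.52) {
    do.call(rbind, lapply(seq_len(n_birds), function(i) {
      male <- i <= round(0.7 * n_birds)
      dk <- runif(nobs, 30, 800)
      dz <- (dk - mu_d) / sd_d
      tw <- rnorm(nobs, 0, 15)
      hum <- runif(nobs, 40, 95)
      sp <- 72.05 - 10.73 * male + (if (male) b_tw_m else b_tw_f) * tw / 15 +
        8.2 * dz - 8.79 * dz^2 + rnorm(1, 0, 5) + rnorm(nobs, 0, 8)
      data.frame(bird_id = i, sex = if (male) "M" else "F",
                 colony = "c", year = 2015, speed_kmh = sp,
                 cumulative_km = dk, tailwind = tw,
                 crosswind = abs(rnorm(nobs, 0, 10)), humidity = hum,
                 temperature = rnorm(nobs, 22, 3),
                 rain = 0.1 * rpois(nobs, 1),
                 pressure = rnorm(nobs, 1013, 4),
                 cloud_low = runif(nobs), cloud_medium = runif(nobs),
                 cloud_high = runif(nobs))
    }))
  }
  d <- sim_speed()
  f <- suppressMessages(fit_speed_model(d))
  v <- speed_vertex_km(f)
  expect_gt(v, 300); expect_lt(v, 500)
  ct <- f$coef_table
  expect_lt(ct$estimate[ct$term == "sexM"], 0)
  expect_lt(ct$p[ct$term == "tailwind"], 0.05)
  # female tailwind slope stronger than male: negative sexM:tailwind term
  d2 <- sim_speed(b_tw_f = 12, b_tw_m = 2)
  f2 <- suppressMessages(fit_speed_model(d2, sex_tailwind_interaction = TRUE))
  ct2 <- f2$coef_table
  est <- ct2$estimate[grepl("sexM:tailwind", ct2$term)]
  expect_lt(est, 0)
})

test_that("no weather effects in truth leaves weather CIs covering zero", {
  set.seed(44)
  d <- do.call(rbind, lapply(1:25, function(i) {
    nobs <- 20
    data.frame(bird_id = i, sex = sample(c("F", "M"), 1),
               colony = "c", year = 2015,
               speed_kmh = 55 + rnorm(1, 0, 4) + rnorm(nobs, 0, 8),
               cumulative_km = runif(nobs, 30, 800),
               tailwind = rnorm(nobs, 0, 15),
               crosswind = abs(rnorm(nobs, 0, 10)),
               humidity = runif(nobs, 40, 95),
               temperature = rnorm(nobs, 22, 3))
  }))
  f <- suppressMessages(fit_speed_model(d))
  ct <- f$coef_table
  for (tm in c("tailwind", "crosswind", "temperature")) {
    i <- ct$term == tm
    expect_true(ct$ci_lo[i] <= 0 && 0 <= ct$ci_hi[i])
  }
})

test_that("speed table excludes the final segment of every event", {
  sd <- small_dataset()
  tab <- build_speed_table(sd$events, sd$ds$birds, sd$ds$weather)
  for (bid in unique(tab$bird_id)) {
    ev <- sd$events[[bid]]
    seg_all <- segment_kinematics(ev$in_flight)
    final_t <- seg_all$t_from[nrow(seg_all)]
    expect_false(any(abs(as.numeric(tab$t_utc[tab$bird_id == bid]) -
                           as.numeric(final_t)) < 1))
  }
})

test_that("phenology models recover colony timing offsets and day-of-year", {
  expect_equal(day_of_year_local(parse_utc("2015-08-06T10:00:00Z")), 218)
  expect_equal(day_of_year_local(parse_utc("2016-08-06T10:00:00Z")), 219)
  set.seed(45)
  n <- 120
  colony <- sample(c("comacchio", "margherita", "molentargius"), n, TRUE)
  off <- c(comacchio = 20, margherita = 35, molentargius = 0)
  sexm <- rbinom(n, 1, 0.6)
  doy <- 225 + off[colony] - 10 * sexm + rnorm(n, 0, 6)
  sums <- data.frame(bird_id = sprintf("B%03d", 1:n),
                     departure_doy = doy,
                     total_distance_km = runif(n, 100, 800))
  birds <- data.frame(bird_id = sprintf("B%03d", 1:n),
                      sex = ifelse(sexm == 1, "M", "F"), colony = colony,
                      year = 2015, tarsus_mm = rnorm(n, 265, 10),
                      mass_g = rnorm(n, 2900, 220), wing_mm = rnorm(n, 380, 10),
                      smi_g = rnorm(n, 2900, 200))
  fits <- fit_phenology_models(sums, birds)
  expect_named(fits, c("base", "tarsus", "mass", "wing", "smi"))
  ct <- fits$base$coef_table
  # margherita - comacchio = +15 days; molentargius - comacchio = -20 days
  i <- which(ct$term == "colonymargherita")
  expect_true(ct$ci_lo[i] <= 15 && 15 <= ct$ci_hi[i])
  j <- which(ct$term == "colonymolentargius")
  expect_true(ct$ci_lo[j] <= -20 && -20 <= ct$ci_hi[j])
})

test_that("distance model finds a colony effect and ignores absent weather effects", {
  sd <- small_dataset()
  f <- suppressMessages(fit_distance_model(sd$events,
    do.call(rbind, lapply(sd$events, summarize_event)),
    sd$ds$birds, sd$ds$weather))
  expect_s3_class(f, "fledgr_fit")
  expect_true(all(c("estimate", "se", "p") %in% names(f$coef_table)))
  # the synthetic colonies differ in route length: colony terms present
  expect_true(any(grepl("colony", f$coef_table$term)))
})
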