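test_that("configuration validates and rejects malformed fields", {
  cfg <- sim_config(seed = 3)
  expect_s3_class(cfg, "sim_config")
  expect_error(sim_config(nonsense = 1), class = "fledgr_invalid_input")
  bad <- cfg
  bad$colonies$comacchio$destinations$prob <- c(0.5, 0.2, 0.2)
  expect_error(validate_sim_config(bad), class = "fledgr_config_schema")
  bad2 <- cfg
  bad2$fix_interval_h <- -1
  expect_error(validate_sim_config(bad2), class = "fledgr_config_schema")
})

test_that("configuration round-trips through YAML", {
  cfg <- small_cfg(seed = 9)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$colonies$molentargius$destinations,
               cfg$colonies$molentargius$destinations)
  expect_equal(cfg2$hazard, cfg$hazard)
})

test_that("weather generation is deterministic and respects grid invariants", {
  cfg <- small_cfg(seed = 21)
  w1 <- simulate_weather(cfg)
  w2 <- simulate_weather(cfg)
  expect_identical(w1$wind_u$values, w2$wind_u$values)
  expect_identical(w1$temperature$values, w2$temperature$values)
  expect_named(w1, c("temperature", "precipitation", "rel_humidity",
                     "pressure", "wind_u", "wind_v",
                     "cloud_low", "cloud_medium", "cloud_high"),
               ignore.order = TRUE)
  for (g in w1) {
    expect_true(all(is.finite(g$values)))
    expect_equal(dim(g$values),
                 c(length(g$times), length(g$lats), length(g$lons)))
  }
  expect_equal(w1$wind_u$spatial_res_deg, 0.25)
  expect_equal(w1$wind_u$temporal_step_h, 1)
  expect_equal(w1$cloud_low$spatial_res_deg, 0.75)
  expect_equal(w1$cloud_low$temporal_step_h, 6)
  expect_true(all(w1$cloud_low$values >= 0 & w1$cloud_low$values <= 1))
  expect_true(all(w1$precipitation$values >= 0))
})

test_that("bird simulation honours the sex ratio and condition-dependent intent", {
  cfg <- sim_config(seed = 31)
  b <- simulate_birds(cfg)
  expect_equal(nrow(b), 40)
  expect_equal(sum(b$sex == "F"), 11)
  expect_true(all(b$tarsus_mm > 0 & b$mass_g > 0 & b$wing_mm > 0))
  # propensity round-trip at large n: fitted slope covers the generative value
  big <- sim_config(seed = 32, colonies = list(
    molentargius = utils::modifyList(sim_config()$colonies$molentargius,
                                     list(n_birds = 500))),
    n_female = 150)
  bb <- simulate_birds(big)
  f <- fit_propensity(data.frame(migrate = bb$migrate_intent, smi_g = bb$smi_g))
  ci <- confint(f)["smi_g", ]
  expect_true(ci[1] <= big$propensity$slope_per_sd &&
                big$propensity$slope_per_sd <= ci[2])
  expect_gt(coef(f)[["smi_g"]], 0)
  # zero slope: migrant fraction near the intercept probability
  null <- sim_config(seed = 33, propensity = list(slope_per_sd = 0),
                     colonies = big$colonies, n_female = 150)
  bn <- simulate_birds(null)
  expect_lt(abs(mean(bn$migrate_intent) - plogis(null$propensity$intercept)),
            3 * sqrt(0.25 / 500))
})

test_that("forcing the hazard to one departs every migrant at the first window fix", {
  cfg <- small_cfg(seed = 41)
  cfg$hazard$override_p <- 1
  w <- simulate_weather(cfg)
  b <- simulate_birds(cfg)
  tr <- simulate_tracks(cfg, w, b)
  for (bid in names(tr$truth$birds)) {
    t <- tr$truth$birds[[bid]]
    if (t$strategy != "migrant") next
    dep <- parse_utc(t$departure_utc)
    cc <- cfg$colonies[[b$colony[b$bird_id == bid]]]
    earliest <- parse_utc(paste0(cfg$window$depart_earliest, "T00:00:00Z")) +
      cc$depart_offset_days * 86400
    # departure at the first eligible night fix on/after the earliest date
    expect_lt(as.numeric(dep) - as.numeric(earliest), 30 * 3600)
    clk <- (as.numeric(format(dep, "%H", tz = "UTC")) + 2) %% 24  # local clock
    expect_true(clk >= 16 || clk <= 2)
  }
})

test_that("track simulation is deterministic and rejects missing weather coverage", {
  cfg <- small_cfg(seed = 51)
  w <- simulate_weather(cfg)
  b <- simulate_birds(cfg)
  t1 <- simulate_tracks(cfg, w, b)
  t2 <- simulate_tracks(cfg, w, b)
  expect_identical(t1$fixes, t2$fixes)
  short <- w
  for (v in names(short))
    short[[v]] <- weather_grid(v, short[[v]]$times[1:10], short[[v]]$lats,
                               short[[v]]$lons,
                               short[[v]]$values[1:10, , , drop = FALSE])
  expect_error(simulate_tracks(cfg, short, b), class = "fledgr_coverage")
})

test_that("most synthetic departures ride positive tailwinds", {
  sd <- small_dataset()
  tw <- vapply(sd$ds$truth$birds, function(x)
    if (is.null(x$departure_tailwind_kmh)) NA_real_ else x$departure_tailwind_kmh,
    numeric(1))
  tw <- tw[!is.na(tw)]
  expect_gte(mean(tw > 0), 0.7)
})

test_that("segmentation recovers generator truth on the shared scenario", {
  sd <- small_dataset()
  truth_strat <- vapply(sd$ds$truth$birds, `[[`, "", "strategy")
  m <- merge(sd$seg$strategies,
             data.frame(bird_id = names(truth_strat), truth = truth_strat))
  expect_equal(mean(m$strategy == m$truth), 1)
  for (bid in names(sd$seg$events)) {
    dep_true <- parse_utc(sd$ds$truth$birds[[bid]]$departure_utc)
    dep_est <- sd$seg$events[[bid]]$departure_fix$t_utc
    expect_lte(abs(as.numeric(dep_est) - as.numeric(dep_true)) / 3600, 2)
  }
})

test_that("fixture bundles round-trip and are byte-stable under a fixed seed", {
  cfg <- sim_config(
    seed = 61,
    colonies = list(molentargius = utils::modifyList(
      sim_config()$colonies$molentargius, list(n_birds = 3))),
    n_female = 1,
    propensity = list(intercept = -20),   # residents only: tiny bundle
    domain = list(lats = c(38.5, 40), lons = c(8.5, 10)),
    window = list(track_start = "2015-08-01", track_end = "2015-08-04",
                  weather_start = "2015-08-01", weather_end = "2015-08-04",
                  depart_earliest = "2015-08-02", depart_latest = "2015-08-03"))
  ds <- simulate_dataset(cfg)
  dir1 <- file.path(tempfile(), "b1"); dir2 <- file.path(tempfile(), "b2")
  write_fixture_set(ds, dir1)
  expect_error(write_fixture_set(ds, dir1), class = "fledgr_exists")
  write_fixture_set(ds, dir2)
  f1 <- list.files(dir1, full.names = TRUE)
  f2 <- list.files(dir2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  back <- read_fixture_set(dir1)
  expect_equal(back$fixes$lat, ds$fixes$lat)
  expect_equal(back$birds$smi_g, ds$birds$smi_g)
  expect_equal(back$weather$wind_u$values, ds$weather$wind_u$values)
  expect_equal(back$truth$birds[[1]]$strategy, ds$truth$birds[[1]]$strategy)
  expect_equal(back$config$seed, cfg$seed)
})
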