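colony <- geo_point(39.2282, 9.1526)

test_that("segment kinematics computes speed, bearing and cumulative distance", {
  t0 <- parse_utc("2015-08-01T00:00:00Z")
  p2 <- geosphere::destPoint(cbind(colony$lon_deg, colony$lat_deg), 0,
                             100 * 1000, r = 6371008.8)
  fx <- data.frame(t_utc = c(t0, t0 + 2 * 3600),
                   lat = c(colony$lat_deg, p2[1, 2]),
                   lon = c(colony$lon_deg, p2[1, 1]))
  s <- segment_kinematics(fx)
  expect_equal(s$speed_kmh, 50, tolerance = 1e-6)
  expect_equal(s$bearing_deg, 0, tolerance = 1e-6)
  expect_equal(s$cumulative_km, 0)
  # n fixes -> n-2 segments with the final one excluded
  tr <- track_from_plan(colony, list(list(type = "fly", hours = 10,
                                          bearing = 90, speed = 50)))
  expect_equal(nrow(segment_kinematics(tr, exclude_final = TRUE)), nrow(tr) - 2)
  bad <- fx; bad$t_utc <- rev(bad$t_utc)
  expect_error(segment_kinematics(bad), class = "fledgr_invalid_ordering")
})

test_that("sum of segment distances equals the event total distance", {
  tr <- track_from_plan(colony, list(
    list(type = "dwell", hours = 48),
    list(type = "fly", hours = 8, bearing = 170, speed = 55),
    list(type = "dwell", hours = 24 * 25)))
  ev <- migration_event(tr, colony)
  expect_equal(sum(ev$segments$dist_km), ev$total_distance_km, tolerance = 1e-6)
  expect_gte(ev$total_distance_km,
             great_circle_km(geo_point(ev$departure_fix$lat, ev$departure_fix$lon),
                             geo_point(ev$arrival_fix$lat, ev$arrival_fix$lon)) - 1e-9)
  expect_lte(ev$mean_speed_kmh, ev$max_speed_kmh)
})

test_that("strategy classification follows the 100-km and 1-November rules", {
  deadline <- as.Date("2015-11-01")
  # resident: wandering out to ~40 km and back
  res <- track_from_plan(colony, list(
    list(type = "dwell", hours = 24),
    list(type = "fly", hours = 4, bearing = 45, speed = 10),
    list(type = "dwell", hours = 24),
    list(type = "fly", hours = 4, bearing = 225, speed = 10),
    list(type = "dwell", hours = 24 * 30)))
  expect_identical(classify_strategy(res, colony, deadline), "resident")
  # migrant: 330-km flight then a month-long stay, well before the deadline
  mig <- track_from_plan(colony, list(
    list(type = "dwell", hours = 72),
    list(type = "fly", hours = 6, bearing = 185, speed = 55),
    list(type = "dwell", hours = 24 * 30)))
  expect_identical(classify_strategy(mig, colony, deadline), "migrant")
  # same movement but arriving after 1 November: resident by the deadline rule
  late <- track_from_plan(colony, list(
    list(type = "dwell", hours = 72),
    list(type = "fly", hours = 6, bearing = 185, speed = 55),
    list(type = "dwell", hours = 24 * 30)),
    start = parse_utc("2015-11-01T00:00:00Z"))
  expect_identical(classify_strategy(late, colony, deadline), "resident")
})

test_that("departure detection ignores foraging loops and flags truncated starts", {
  dep_truth <- parse_utc("2015-08-01T12:00:00Z") + (36 + 2) * 3600
  tr <- track_from_plan(colony, list(
    list(type = "dwell", hours = 12),
    list(type = "fly", hours = 2, bearing = 90, speed = 30),  # 60-km loop out
    list(type = "fly", hours = 2, bearing = 270, speed = 30), # and back
    list(type = "dwell", hours = 20),
    list(type = "fly", hours = 8, bearing = 185, speed = 55), # real departure
    list(type = "dwell", hours = 24 * 30)))
  idx <- detect_departure(tr, colony)
  expect_lte(abs(as.numeric(tr$t_utc[idx]) - as.numeric(dep_truth)), 2 * 3600)
  # the 60-km loop must not be picked
  expect_gt(as.numeric(tr$t_utc[idx]),
            as.numeric(parse_utc("2015-08-01T12:00:00Z")) + 20 * 3600)
  # track starting beyond the radius: first fix, with a data-quality warning
  far <- tr[tr$t_utc >= dep_truth + 4 * 3600, ]
  expect_warning(idx2 <- detect_departure(far, colony),
                 class = "fledgr_data_quality")
  expect_equal(idx2, 1L, ignore_attr = TRUE)
  # no qualifying excursion at all
  expect_error(detect_departure(tr[1:8, ], colony),
               class = "fledgr_no_departure")
})

test_that("arrival and stopover rules respect the 12-h and 20-day thresholds", {
  # 13-h pause en route is a stopover, not the arrival
  tr <- track_from_plan(colony, list(
    list(type = "dwell", hours = 24),
    list(type = "fly", hours = 4, bearing = 185, speed = 55),
    list(type = "dwell", hours = 13),
    list(type = "fly", hours = 4, bearing = 185, speed = 55),
    list(type = "dwell", hours = 24 * 30)))
  dep <- detect_departure(tr, colony)
  arr <- detect_arrival_and_stopovers(tr, dep)
  expect_equal(nrow(arr$stopovers), 1)
  expect_gte(arr$stopovers$dwell_h[1], 12)
  # arrival is the first fix of the terminal dwell
  d_arr <- great_circle_km(geo_point(tr$lat[arr$arrival_idx],
                                     tr$lon[arr$arrival_idx]),
                           geo_point(tr$lat[nrow(tr)], tr$lon[nrow(tr)]))
  expect_lt(d_arr, 15)
  # a 19-day stay followed by onward movement is a stopover, not the end
  tr19 <- track_from_plan(colony, list(
    list(type = "dwell", hours = 24),
    list(type = "fly", hours = 4, bearing = 185, speed = 55),
    list(type = "dwell", hours = 24 * 19),
    list(type = "fly", hours = 4, bearing = 185, speed = 55),
    list(type = "dwell", hours = 24 * 25)))
  dep19 <- detect_departure(tr19, colony)
  arr19 <- detect_arrival_and_stopovers(tr19, dep19)
  expect_equal(nrow(arr19$stopovers), 1)
  expect_gte(arr19$stopovers$dwell_h[1], 19 * 24 - 2)
  expect_gt(arr19$arrival_idx, arr19$stopovers$exit_idx[1])
  # no dwell long enough before the data end: open-ended event
  open <- track_from_plan(colony, list(
    list(type = "dwell", hours = 24),
    list(type = "fly", hours = 4, bearing = 185, speed = 55),
    list(type = "dwell", hours = 24 * 5)))
  expect_error(detect_arrival_and_stopovers(open, detect_departure(open, colony)),
               class = "fledgr_open_ended_event")
})

test_that("event summaries are internally consistent", {
  tr <- track_from_plan(colony, list(
    list(type = "dwell", hours = 48),
    list(type = "fly", hours = 6, bearing = 170, speed = 60),
    list(type = "dwell", hours = 24 * 28)))
  ev <- migration_event(tr, colony)
  s <- summarize_event(ev)
  expect_equal(s$duration_h,
               (as.numeric(ev$arrival_fix$t_utc) -
                  as.numeric(ev$departure_fix$t_utc)) / 3600)
  expect_equal(s$total_distance_km, sum(ev$segments$dist_km))
  expect_lte(s$mean_speed_kmh, s$max_speed_kmh)
})

test_that("fix gaps inside a dwell void its certificate with a warning", {
  tr <- track_from_plan(colony, list(
    list(type = "dwell", hours = 24),
    list(type = "fly", hours = 4, bearing = 185, speed = 55),
    list(type = "dwell", hours = 24 * 30)))
  dep <- detect_departure(tr, colony)
  # carve a 16-h hole inside the terminal dwell
  arr_first <- detect_arrival_and_stopovers(tr, dep)$arrival_idx
  hole <- tr$t_utc > tr$t_utc[arr_first + 2] &
    tr$t_utc <= tr$t_utc[arr_first + 2] + 16 * 3600
  expect_warning(
    try(detect_arrival_and_stopovers(tr[!hole, ], dep), silent = TRUE),
    class = "fledgr_data_quality")
})

test_that("Movebank-style fix CSV round-trips", {
  tr <- track_from_plan(colony, list(list(type = "fly", hours = 6,
                                          bearing = 100, speed = 48)))
  path <- tempfile(fileext = ".csv")
  write_fixes_csv(tr, path)
  tr2 <- read_fixes_csv(path)
  expect_equal(tr2$lat, tr$lat)
  expect_equal(tr2$lon, tr$lon)
  expect_equal(as.numeric(tr2$t_utc), as.numeric(tr$t_utc))
  expect_error(read_fixes_csv(path2 <- {
    p <- tempfile(fileext = ".csv"); writeLines("a,b\n1,2", p); p
  }), class = "fledgr_invalid_input")
})
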