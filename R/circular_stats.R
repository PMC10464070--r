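## Circular statistics: Rayleigh uniformity test, 60-degree direction binning,
## seasonal wind-direction frequencies at a colony, and the Poisson GLM
## relating departure-direction frequencies to wind-direction frequencies.

#' Rayleigh test of circular uniformity
#'
#' Mean resultant length `r = |sum(exp(i theta))| / n`, statistic
#' `Z = n r^2`, p-value by the standard series approximation
#' (Zar-style correction in 1/n and 1/n^2).
#'
#' @param angles_deg angles in degrees (n >= 3).
#' @return list: `n`, `r_bar`, `mean_direction_deg`, `z`, `p`.
#' @export
rayleigh_test <- function(angles_deg) {
  angles_deg <- angles_deg[is.finite(angles_deg)]
  n <- length(angles_deg)
  if (n < 3)
    stop_fledgr("Rayleigh test needs at least 3 angles", "fledgr_insufficient_data")
  th <- deg2rad(angles_deg)
  C <- mean(cos(th)); S <- mean(sin(th))
  r <- sqrt(C^2 + S^2)
  z <- n * r^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  list(n = n, r_bar = r,
       mean_direction_deg = if (r > 1e-12) norm_angle_deg(rad2deg(atan2(S, C)))
                            else NA_real_,
       z = z, p = p)
}

#' Bin angles into six 60-degree classes
#'
#' Equal half-open classes `[0,60), [60,120), ..., [300,360)` after
#' normalizing angles into `[0, 360)`.
#'
#' @param angles_deg finite angles in degrees.
#' @return integer vector of 6 counts, named by class.
#' @export
bin_directions <- function(angles_deg) {
  if (!is_finite_num(angles_deg) && length(angles_deg) > 0)
    stop_fledgr("non-finite angles", "fledgr_invalid_input")
  a <- norm_angle_deg(angles_deg)
  idx <- pmin(floor(a / 60) + 1, 6)
  counts <- tabulate(idx, nbins = 6)
  names(counts) <- sprintf("[%d,%d)", seq(0, 300, 60), seq(60, 360, 60))
  counts
}

#' Seasonal wind-direction frequencies at a colony
#'
#' Samples the blowing-toward wind direction at the colony location every
#' `step_h` hours across the period (first to last departure) and bins it into
#' the six 60-degree classes. Mean wind speed per bin is attached for
#' rose-chart export.
#'
#' @param weather named list of [weather_grid()]s containing `wind_u`,
#'   `wind_v`.
#' @param colony a [geo_point()].
#' @param period POSIXct length-2 (start, end), typically first and last
#'   departure time.
#' @param step_h sampling interval in hours (2, the fix cadence).
#' @return list: `counts` (6 bins), `n_steps`, `mean_speed_kmh` per bin,
#'   `angles_deg` (the sampled directions).
#' @export
seasonal_wind_frequencies <- function(weather, colony, period, step_h = 2) {
  period <- as.POSIXct(period, tz = "UTC")
  tt <- seq(period[1], period[2], by = step_h * 3600)
  u <- interpolate_at(weather$wind_u, colony$lat_deg, colony$lon_deg, tt)
  v <- interpolate_at(weather$wind_v, colony$lat_deg, colony$lon_deg, tt)
  wd <- wind_speed_dir(u, v)
  ok <- !is.na(wd$dir_to)
  counts <- bin_directions(wd$dir_to[ok])
  bin_idx <- pmin(floor(norm_angle_deg(wd$dir_to[ok]) / 60) + 1, 6)
  mean_speed <- vapply(1:6, function(b) {
    s <- wd$speed[ok][bin_idx == b]
    if (length(s)) mean(s) * 3.6 else NA_real_
  }, numeric(1))
  names(mean_speed) <- names(counts)
  list(counts = counts, n_steps = length(tt), mean_speed_kmh = mean_speed,
       angles_deg = wd$dir_to[ok])
}

#' Poisson GLM of departure-direction vs wind-direction frequencies
#'
#' Departure counts in the six 60-degree classes (response) against the
#' wind-direction frequencies in the same classes, one model per colony;
#' Poisson error, log link. The wind-frequency covariate is centred and
#' scaled. The Pearson dispersion statistic is attached. With six
#' observations per colony inference is fragile; results are exact but should
#' be read with that caveat.
#'
#' @param departure_counts integer vector of 6 departure counts.
#' @param wind_counts integer vector of 6 wind-frequency counts.
#' @return a [fledgr_fit] (slope term `wind_freq`).
#' @export
fit_direction_wind_glm <- function(departure_counts, wind_counts) {
  if (sum(departure_counts) == 0)
    stop_fledgr("all-zero departure counts: degenerate fit", "fledgr_degenerate_fit")
  df <- data.frame(dep = as.numeric(departure_counts),
                   wind_freq = as.numeric(wind_counts))
  fit_glm(dep ~ wind_freq, data = df, family = stats::poisson(),
          standardize = TRUE)
}
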