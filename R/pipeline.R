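## Pipeline orchestration: simulate -> segment -> annotate -> fit -> report,
## every stage reading and writing files under one run directory, plus a
## reproducibility manifest (config/input hashes, seed, versions, row counts,
## warnings). Stage outputs are deterministic for a given seed.

.pipe_paths <- function(outdir) {
  list(config = file.path(outdir, "config.yaml"),
       fixes = file.path(outdir, "fixes.csv"),
       biometrics = file.path(outdir, "biometrics.csv"),
       truth = file.path(outdir, "truth.json"),
       weather = file.path(outdir, "weather_cache.rds"),
       strategies = file.path(outdir, "strategies.csv"),
       events = file.path(outdir, "event_summaries.csv"),
       events_rds = file.path(outdir, "events_cache.rds"),
       cases = file.path(outdir, "departure_cases.csv"),
       speed = file.path(outdir, "speed_segments.csv"),
       fitdir = file.path(outdir, "fits"),
       report = file.path(outdir, "report.json"),
       manifest = file.path(outdir, "manifest.json"))
}

.write_table <- function(df, path) {
  df2 <- df
  num <- vapply(df2, is.numeric, logical(1))
  df2[num] <- lapply(df2[num], function(x) sprintf("%.10g", x))
  if (inherits(df2$t_utc, "POSIXct")) df2$t_utc <- format_utc(df$t_utc)
  utils::write.csv(df2, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` (synthetic dataset under the config seed), `segment`
#' (strategies + migration events), `annotate` (case-control and speed
#' tables), `fit` (all study models + circular analysis), `report` (headline
#' summary JSON), or `all`. Each stage reads its inputs from, and writes its
#' outputs under, `outdir`; a manifest records hashes, seed, versions, row
#' counts and warnings. Re-running a stage with identical inputs reproduces
#' identical outputs.
#'
#' @param stage one of `simulate, segment, annotate, fit, report, all`.
#' @param config a [sim_config()] or path to a YAML config.
#' @param outdir run directory (created if needed).
#' @param overwrite allow reuse of an existing run directory.
#' @param quiet suppress progress messages.
#' @return the manifest (invisibly).
#' @export
run_pipeline <- function(stage = "all", config = sim_config(), outdir,
                         overwrite = FALSE, quiet = TRUE) {
  stage <- match.arg(stage, c("simulate", "segment", "annotate", "fit",
                              "report", "all"))
  if (is.character(config)) config <- read_sim_config(config)
  validate_sim_config(config)
  if (dir.exists(outdir) && !overwrite && stage %in% c("simulate", "all") &&
      length(list.files(outdir)))
    stop_fledgr(sprintf("'%s' exists and is not empty; set overwrite = TRUE",
                        outdir), "fledgr_exists")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- .pipe_paths(outdir)
  dir.create(p$fitdir, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))
  counts <- list()

  stages <- if (stage == "all")
    c("simulate", "segment", "annotate", "fit", "report") else stage

  if ("simulate" %in% stages) {
    say("simulate: seed %d", config$seed)
    ds <- withCallingHandlers(simulate_dataset(config), warning = note)
    write_sim_config(config, p$config)
    write_fixes_csv(ds$fixes, p$fixes)
    .write_table(ds$birds, p$biometrics)
    jsonlite::write_json(ds$truth, p$truth, auto_unbox = TRUE, digits = NA,
                         null = "null")
    saveRDS(ds$weather, p$weather)
    counts$fixes <- nrow(ds$fixes); counts$birds <- nrow(ds$birds)
  }

  if ("segment" %in% stages) {
    for (f in c(p$fixes, p$biometrics))
      if (!file.exists(f))
        stop_fledgr(sprintf("missing input '%s': run the simulate stage first", f),
                    "fledgr_missing_input")
    fixes <- read_fixes_csv(p$fixes)
    birds <- utils::read.csv(p$biometrics, stringsAsFactors = FALSE)
    deadline <- as.Date(sprintf("%d-11-01", config$year))
    seg <- withCallingHandlers(
      segment_all_tracks(fixes, birds, config$colonies, deadline),
      warning = note)
    .write_table(seg$strategies, p$strategies)
    sums <- do.call(rbind, lapply(seg$events, summarize_event))
    .write_table(sums, p$events)
    saveRDS(seg$events, p$events_rds)
    counts$migrants <- length(seg$events)
    counts$residents <- sum(seg$strategies$strategy == "resident")
  }

  if ("annotate" %in% stages) {
    for (f in c(p$events_rds, p$weather))
      if (!file.exists(f))
        stop_fledgr(sprintf("missing input '%s': run earlier stages first", f),
                    "fledgr_missing_input")
    events <- readRDS(p$events_rds)
    weather <- readRDS(p$weather)
    fixes <- read_fixes_csv(p$fixes)
    birds <- utils::read.csv(p$biometrics, stringsAsFactors = FALSE)
    events <- attach_pre_departure(events, fixes)
    cases <- withCallingHandlers(
      build_departure_cases(events, birds, config$colonies, weather),
      warning = note)
    .write_table(cases, p$cases)
    spd <- withCallingHandlers(
      build_speed_table(events, birds, weather), warning = note)
    .write_table(spd, p$speed)
    saveRDS(events, p$events_rds)
    counts$case_control_rows <- nrow(cases)
    counts$speed_segments <- nrow(spd)
  }

  if ("fit" %in% stages) {
    for (f in c(p$cases, p$speed, p$events_rds))
      if (!file.exists(f))
        stop_fledgr(sprintf("missing input '%s': run the annotate stage first", f),
                    "fledgr_missing_input")
    birds <- utils::read.csv(p$biometrics, stringsAsFactors = FALSE)
    strategies <- utils::read.csv(p$strategies, stringsAsFactors = FALSE)
    sums <- utils::read.csv(p$events, stringsAsFactors = FALSE)
    cases <- utils::read.csv(p$cases, stringsAsFactors = FALSE)
    cases$t_utc <- parse_utc(cases$t_utc)
    spd <- utils::read.csv(p$speed, stringsAsFactors = FALSE)
    events <- readRDS(p$events_rds)
    weather <- readRDS(p$weather)
    wfit <- function(expr) withCallingHandlers(expr, warning = note)

    ## condition / propensity
    bio <- merge(birds, strategies, by = "bird_id")
    bio$migrate <- as.integer(bio$strategy == "migrant")
    biofits <- wfit(fit_biometric_models(bio))
    for (nm in names(biofits))
      write_fit_csv(biofits[[nm]], file.path(p$fitdir, paste0("biometric_", nm, ".csv")))
    prop <- if (length(unique(bio$migrate)) > 1) wfit(fit_propensity(bio)) else NULL
    if (!is.null(prop)) write_fit_csv(prop, file.path(p$fitdir, "propensity.csv"))

    ## departure GLMM (+ distance interaction)
    depfit <- wfit(fit_departure_model(cases, semipartial = TRUE))
    write_fit_csv(depfit, file.path(p$fitdir, "departure_model.csv"))
    depint <- wfit(fit_departure_distance_interaction(cases))
    write_fit_csv(depint, file.path(p$fitdir, "departure_interaction.csv"))

    ## speed LMM (+ sex x tailwind)
    spdfit <- wfit(fit_speed_model(spd, semipartial = TRUE))
    write_fit_csv(spdfit, file.path(p$fitdir, "speed_model.csv"))
    spdsex <- wfit(fit_speed_model(spd, sex_tailwind_interaction = TRUE))
    write_fit_csv(spdsex, file.path(p$fitdir, "speed_sex_tailwind.csv"))

    ## phenology
    phen <- wfit(fit_phenology_models(sums, birds))
    for (nm in names(phen))
      write_fit_csv(phen[[nm]], file.path(p$fitdir, paste0("phenology_", nm, ".csv")))

    ## distance
    dfit <- wfit(fit_distance_model(events, sums, birds, weather))
    write_fit_csv(dfit, file.path(p$fitdir, "distance_model.csv"))

    ## circular: per-colony wind roses, Rayleigh, direction-vs-wind GLM
    dir_rows <- list()
    for (cn in names(config$colonies)) {
      cc <- config$colonies[[cn]]
      ids <- birds$bird_id[birds$colony == cn]
      evs <- events[names(events) %in% ids]
      if (!length(evs)) next
      brgs <- vapply(evs, `[[`, 1, "destination_bearing_deg")
      dep_t <- as.POSIXct(vapply(evs, function(e)
        as.numeric(e$departure_fix$t_utc), numeric(1)),
        origin = "1970-01-01", tz = "UTC")
      period <- range(dep_t)
      if (diff(as.numeric(period)) < 86400) period[2] <- period[1] + 86400
      wf <- seasonal_wind_frequencies(weather, geo_point(cc$lat, cc$lon), period)
      dep_bins <- bin_directions(brgs)
      ray_wind <- rayleigh_test(wf$angles_deg)
      ray_dep <- if (length(brgs) >= 3) rayleigh_test(brgs) else NULL
      gfit <- tryCatch(fit_direction_wind_glm(dep_bins, wf$counts),
                       error = function(e) NULL)
      sl <- if (!is.null(gfit))
        gfit$coef_table[gfit$coef_table$term == "wind_freq", ] else NULL
      dir_rows[[cn]] <- data.frame(
        colony = cn, n_migrants = length(evs),
        wind_rbar = ray_wind$r_bar, wind_rayleigh_p = ray_wind$p,
        dep_rbar = ray_dep$r_bar %||% NA_real_,
        dep_rayleigh_p = ray_dep$p %||% NA_real_,
        glm_slope = sl$estimate %||% NA_real_,
        glm_p = sl$p %||% NA_real_,
        glm_dispersion = gfit$stats$dispersion %||% NA_real_)
      rose <- data.frame(bin = names(wf$counts), wind_count = as.integer(wf$counts),
                         wind_mean_speed_kmh = wf$mean_speed_kmh,
                         departure_count = as.integer(dep_bins))
      .write_table(rose, file.path(p$fitdir, paste0("wind_rose_", cn, ".csv")))
    }
    .write_table(do.call(rbind, dir_rows), file.path(p$fitdir, "direction_wind.csv"))
    counts$fit_tables <- length(list.files(p$fitdir))
  }

  if ("report" %in% stages) {
    if (!dir.exists(p$fitdir) || !length(list.files(p$fitdir)))
      stop_fledgr("no fit outputs: run the fit stage first",
                  "fledgr_missing_input")
    strategies <- utils::read.csv(p$strategies, stringsAsFactors = FALSE)
    sums <- utils::read.csv(p$events, stringsAsFactors = FALSE)
    cases <- utils::read.csv(p$cases, stringsAsFactors = FALSE)
    dep_tw <- cases$tailwind[cases$label == 1]
    dep <- utils::read.csv(file.path(p$fitdir, "departure_model.csv"),
                           stringsAsFactors = FALSE)
    spdf <- utils::read.csv(file.path(p$fitdir, "speed_model.csv"),
                            stringsAsFactors = FALSE)
    spd <- utils::read.csv(p$speed, stringsAsFactors = FALSE)
    report <- list(
      n_birds = nrow(strategies),
      n_migrants = sum(strategies$strategy == "migrant"),
      migrant_pct = 100 * mean(strategies$strategy == "migrant"),
      tailwind_departure_pct = 100 * mean(dep_tw > 0),
      mean_departure_tailwind_kmh = mean(dep_tw),
      mean_speed_kmh = mean(spd$speed_kmh),
      max_speed_kmh = max(spd$speed_kmh),
      mean_distance_km = mean(sums$total_distance_km),
      departure_tailwind_estimate = dep$estimate[dep$term == "tailwind"],
      speed_sex_m_estimate = spdf$estimate[spdf$term == "sexM"],
      speed_cumdist2_estimate = spdf$estimate[spdf$term == "I(cumulative_km^2)"]
    )
    jsonlite::write_json(report, p$report, auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    stage = stage,
    seed = config$seed,
    config_hash = unname(tools::md5sum(p$config)),
    input_hashes = {
      h <- tools::md5sum(Filter(file.exists,
        c(p$fixes, p$biometrics, p$strategies, p$events, p$cases, p$speed)))
      stats::setNames(as.list(h), basename(names(h)))
    },
    versions = list(fledgr = as.character(utils::packageVersion("fledgr")),
                    r = paste(R.version$major, R.version$minor, sep = ".")),
    counts = counts,
    warnings = warnings_log)
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
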