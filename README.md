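# fledgr

Analysis of the **first (post-fledging) migration** of GPS-tagged juvenile
waterbirds in a partially migratory population — built around the study
design used for Mediterranean greater flamingos: three natal colonies,
solar-GSM tags recording a fix every 2 h from August to November, gridded
reanalysis weather, and a resident-or-migrant decision made once per bird.

The package covers the full chain from raw fixes to fitted models:

* **Geodesy & solar timing** — haversine great-circle distances
  (R = 6371.0088 km), initial bearings, NOAA-style sunset/sunrise, and
  signed *hours after sunset* (after-midnight fixes are referenced to the
  previous evening's sunset).
* **Weather annotation** — dense `[time, lat, lon]` grids (0.25° / 1 h;
  cloud cover 0.75° / 6 h), bilinear-in-space and linear-in-time
  interpolation to any fix, and wind decomposition. With wind speed `v`
  (m/s) and angular deviation `x` between the flight direction and the
  blowing-toward wind direction, the **tailwind** component is
  `3.6 · v · cos(x)` km/h (negative = headwind) and the **crosswind**
  component is `|3.6 · v · sin(x)|` km/h.
* **Track segmentation** — a bird is a **migrant** when it departs on a
  flight beyond a 100-km radius of the colony *and* arrives at its
  non-breeding site before 1 November of the hatch year; departure is the
  first in-flight fix after leaving the colony; arrival is the first fix,
  after a directed movement above 100 km/day, of a dwell held ≥ 20 days;
  en-route dwells ≥ 12 h are stopovers.
* **Body condition** — the Scaled Mass Index
  `SMI_i = mass_i · (tarsus_0 / tarsus_i)` with sex-specific reference
  tarsus (males 275 mm, females 247 mm), plus the standardized-major-axis
  exponent variant.
* **The study models** — condition-dependent migration propensity
  (logistic), phenology LMs (departure day of year), a **case-control
  binomial GLMM** for the nightly departure decision (label 1 = the first
  in-flight fix with *colony* weather; label 0 = every 16:00–02:00 local fix
  in the preceding 72 h; random intercept per bird; VIF-screened,
  standardized predictors; optional tailwind × migration-distance
  interaction), a **speed LMM** on consecutive-fix speeds (final segment
  excluded; quadratic humidity and cumulative distance; optional
  sex × tailwind interaction), a migration-distance LM with
  route-averaged weather, and circular statistics (Rayleigh test,
  six 60° direction classes, departure-direction ~ wind-frequency Poisson
  GLMs per colony).
* **A seeded synthetic-data generator** — colonies at the real coordinates,
  ~40 juveniles (11 F / 29 M), colony-specific prevailing-wind regimes,
  condition-dependent migration intent, wind-triggered nocturnal departures
  simulated from the study's standardized hazard coefficients, and
  per-segment speeds from the standardized speed coefficients (concave in
  cumulative distance with the vertex at 400 km). Every run carries a
  ground-truth record, so segmentation and model recovery are testable end
  to end without any field data.

## Worked example

```r
library(fledgr)

cfg <- sim_config(seed = 1)                    # the default synthetic study
run_pipeline("all", cfg, outdir = "runs/demo") # simulate -> segment ->
                                               # annotate -> fit -> report

rep <- jsonlite::read_json("runs/demo/report.json")
str(rep[c("n_migrants", "migrant_pct", "tailwind_departure_pct",
          "mean_speed_kmh", "departure_tailwind_estimate")])
#> List of 5
#>  $ n_migrants                : int 30
#>  $ migrant_pct               : num 75
#>  $ tailwind_departure_pct    : num 73.3
#>  $ mean_speed_kmh            : num 53.7
#>  $ departure_tailwind_estimate: num 0.938
```

Of the 40 simulated juveniles, 30 migrated (75%); 73.3% of them departed
with a positive tailwind component; in-flight segments averaged 53.7 km/h;
and the fitted case-control GLMM recovered a positive standardized tailwind
effect (0.94) on the nightly departure probability. Per-model coefficient
tables (estimate, SE, 95% CI, Wald type-III statistic, p) are written under
`runs/demo/fits/`, with the run manifest (hashes, seed, versions, row
counts) in `manifest.json`.

A thin shell entry point with the same stages lives at
`inst/scripts/fledgr`:

```sh
Rscript inst/scripts/fledgr --stage all --seed 1 --outdir runs/demo
```

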