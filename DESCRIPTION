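Package: fledgr
Title: Post-Fledging Migration Analysis from GPS Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the first (post-fledging) migration of
    GPS-tagged juvenile waterbirds in a partially migratory population.
    Segments raw fix streams into resident/migrant strategies and migration
    events (departure, stopovers, arrival), annotates tracks with gridded
    weather interpolated in space and time (including tailwind/crosswind
    support relative to the flight direction), computes scaled-mass-index
    body condition, and fits the study analyses: condition-dependent
    migration propensity, phenology linear models, a case-control binomial
    GLMM for nocturnal departure decisions, a linear mixed model for
    in-flight speed, circular statistics (Rayleigh test, 60-degree
    direction binning) relating departure directions to seasonal winds, and
    a migration-distance model. A seeded synthetic-data generator emulates
    the study design (three Mediterranean colonies, 2-h fixes,
    colony-specific wind regimes, wind-triggered nocturnal departures) so
    the whole pipeline is testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    geosphere,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
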