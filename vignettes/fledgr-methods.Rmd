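---
title: "Models and methods behind fledgr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fledgr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

fledgr analyses the first autumn migration of GPS-tagged juvenile waterbirds
in a partially migratory population. This vignette explains the models and
procedures the package implements, the assumptions behind them, the knobs
worth knowing about, and what the synthetic-data generator does and does not
emulate.

## The scientific setting

Juveniles fledge at a natal colony in late summer. Some leave on a single
directed flight to a non-breeding wetland up to several hundred kilometres
away; the rest remain residents near the colony. Tags record a position
every 2 h, so a migration appears as a handful of long fast steps between
months of small-scale wandering. The questions the package's analyses
address are: who migrates (body condition), when (phenology and the
night-by-night departure decision), how fast (in-flight speed and its
covariates), how far, and in which direction relative to the prevailing
winds.

## Geodesy, time, and solar events

Distances are haversine great-circle distances on a sphere of mean radius
6371.0088 km. At the scales involved (≤ ~1000 km) this is within 0.5% of an
ellipsoidal geodesic, and it is exactly reproducible; ellipsoidal geodesics
are deliberately out of scope. Bearings are spherical initial bearings,
degrees clockwise from true north in [0, 360).

Civil local time follows the study region's rule — UTC+2 under daylight
saving, UTC+1 after the switch at the last Sunday of October — implemented
directly (not via the OS timezone database) so results are identical on any
machine; a fixed offset can be supplied for other regions.

Sunset and sunrise use standard NOAA-style solar geometry at zenith 90.833°
(atmospheric refraction plus the solar radius). The covariate *hours after
sunset* is 0 at sunset and positive after; fixes between midnight and the
morning are referenced to the previous evening's sunset by always taking
the nearest sunset in time, which keeps the covariate continuous across
midnight. Polar day/night are flagged rather than raised; the quantity is
then undefined and the functions refuse to compute it. One labelling
inconsistency in the source material (a table header saying "hours before
sunset" against prose saying "after") is resolved in favour of the prose:
positive after sunset.

## Weather grids and wind support

Weather is held as dense `[time, lat, lon]` arrays, one per variable, at
reanalysis granularity: 0.25° and 1 h for temperature, precipitation,
relative humidity, surface pressure and the U/V wind components; 0.75° and
6 h for low/medium/high cloud cover. Interpolation to a fix is bilinear in
latitude–longitude on the two bracketing time slices, then linear in time —
cloud grids included, with no nearest-neighbour fallback. Queries outside
the grid hull raise an error rather than clamping silently: a silently
clamped covariate is a wrong covariate.

Wind is stored as the *blowing-toward* bearing (`atan2(u, v)`), matching the
rose-chart convention used for reporting. Tailwind and crosswind components
are `3.6·v·cos(x)` and `|3.6·v·sin(x)|` km/h. Two flight-direction
conventions are used on purpose: the **route** bearing
(departure → arrival) for the departure model and the seasonal direction
analysis, and the **segment** bearing (consecutive fixes) for the speed
model. The identity tailwind² + crosswind² = (3.6·v)² holds to machine
precision and is enforced in the tests.

Grid I/O uses a long-format CSV dialect (`variable,time_iso8601,lat,lon,value`)
that round-trips losslessly and suits desk-scale fixtures; at full pipeline
scale grids are cached as RDS inside the run directory.

## Segmentation rules

The classification rules are deterministic:

* **migrant** — departs on an excursion beyond a 100-km radius of the
  colony *and* arrives at the non-breeding site before 1 November (local
  civil date) of the hatch year; otherwise **resident**.
* **departure** — the first in-flight fix of the excursion that crosses
  100 km. "In flight" is not defined by the source rules, so the package
  declares one: segment speed to the next fix ≥ 20 km/h while moving away
  from the colony (flight speeds for these birds are ≥ ~45 km/h; foraging
  moves are much slower). The threshold, the 5-km colony residence radius,
  and the 15-km dwell membership radius are configurable
  (`segmentation_params()`); they are the package's declared choices, not
  inferences about unstated ones.
* **arrival** — the first fix of a dwell held at least 20 days, reached
  after a directed movement exceeding 100 km/day. The displacement rate is
  evaluated as the maximum over fixes within the 24 h before the dwell
  entry (never reaching back before the departure) of displacement over
  elapsed time; taking the maximum rather than one fixed 24-h window keeps
  a fast final approach from being masked by a stopover that ended shortly
  before arrival. En-route dwells of at least 12 h are stopovers; a dwell
  held ≥ 12 h but < 20 days is never the arrival.
* Fix gaps longer than 12 h inside a candidate dwell void its duration
  certificate and raise a data-quality warning instead of silently passing.
* Tracks that begin already beyond 100 km return their first fix as the
  departure, flagged with a warning.

Speed analyses drop the final segment of each event (the arrival moment is
unknown within a 2-h fix interval, so the last segment is biased low) and
segments slower than 20 km/h (dwell jitter, not flight).

## The five analyses

**Migration propensity.** Logistic regression of migrate (0/1) on the
Scaled Mass Index, `SMI_i = mass_i · (tarsus_0 / tarsus_i)` with reference
tarsus 275 mm (males) and 247 mm (females). The printed formula carries
scaling exponent 1 and that is the default; the standardized-major-axis
variant `mass · (tarsus_0/tarsus)^b_SMA` is available because the exponent-1
form is a degenerate case of the canonical index and which one the source
used is not decidable from its text. McFadden's R² (1 − ℓ/ℓ₀) is reported.

**Phenology.** One Gaussian LM per biometric: departure day of year
(local civil date; 1 = 1 January) on sex, colony, sex × colony, year and
total migration distance, with each biometric/SMI added individually to
avoid collinearity.

**Departure decision.** A case-control binomial GLMM with logit link and a
random intercept per bird. Per migrant: one label-1 row at the departure
fix, carrying the *colony* weather at that time (the decision is made at
the colony, not en route), and label-0 rows for every fix in the nightly
window within the 72 h before departure. The nightly window is local
[16:00, 24:00) ∪ [00:00, 02:00], both printed endpoints included.
Predictors: tailwind and crosswind toward the route bearing, wind speed,
pressure, humidity, three cloud layers, temperature, rain, sex, colony
(reference: Comacchio), year, and hours after sunset with its quadratic.
Continuous predictors are centred and scaled; collinearity is screened by
iteratively removing the highest VIF ≥ 3 and re-checking. A second fit adds
the tailwind × migration-distance interaction (do birds facing longer
journeys wait for stronger tailwinds?).

**Speed.** A Gaussian LMM on consecutive-fix speeds with random intercept
per bird: sex, colony, year, weather at the segment start (tailwind and
crosswind toward the segment bearing, quadratic humidity), and cumulative
distance with its quadratic. The concave distance profile peaks at
`vertex = center − scale · b₁ / (2 b₂)` km, back-transformed from the
standardized scale (`speed_vertex_km()`). A focused variant adds
sex × tailwind.

**Distance and direction.** Total migration distance is modelled by LM on
weather averaged (unweighted) over the annotated in-flight fixes, plus sex,
colony and departure date. Direction uses circular statistics: the Rayleigh
test (mean resultant length r̄, statistic Z = n r̄², series p-approximation)
and six half-open 60° classes [0,60), …, [300,360). The printed class edges
in the source are internally inconsistent (one 80° class); equal 60° bins
implement the stated intent. Departure-direction counts per colony are
regressed on the colony's seasonal wind-direction frequencies (sampled at
the colony every 2 h between the first and last departure) by Poisson GLM,
with the Pearson dispersion statistic attached. With six observations per
colony this inference is fragile; the package reports exact results and
leaves the caveat in place.

## Estimation machinery

LMs and GLMs use base R; mixed models use lme4 (REML for the Gaussian LMM;
Laplace approximation for the binomial GLMM, with adaptive Gauss–Hermite
quadrature available via `nAGQ`). Per-term F tests for the LMM use the
Satterthwaite degree-of-freedom approximation via lmerTest; Kenward–Roger
is accepted when its support package is installed, and the difference is
immaterial at the scales involved. Every fit is returned as a `fledgr_fit`
with a tidy coefficient table (estimate, SE, 95% CI as estimate ± 1.96·SE
on the link scale, statistic, p), Wald type-III χ² per term block
(β̂ᵀV⁻¹β̂), and fit statistics.

Variance-explained measures are declared, deterministic definitions:
marginal R² is the fixed-effects variance partition
var(Xβ̂) / (var(Xβ̂) + Σ random-effect variance + distribution variance),
with distribution variance σ² (Gaussian), π²/3 (binomial logit) or
log(1 + 1/λ̄) (Poisson log); the semi-partial R² of a predictor is the drop
in marginal R² when the model is refitted without that term. The exact
estimators behind the corresponding published numbers are not spelled out
in the source, so these definitions are stated and used consistently.
Complete separation in logistic fits is flagged in the fit's notes rather
than silently returned; rank-deficient designs produce an aliased-term
report, not a crash.

## The synthetic-data generator

The generator is first-class, tested code. Its defaults *are* the study
conditions: three colonies at the real coordinates (Molentargius,
Comacchio, Margherita di Savoia), 40 juveniles (11 females / 29 males),
2-h fixes, tracks from 1 August, weather grids at the granularities above,
and departures only in the nightly window from 5 August (plus a
colony-specific offset of 0/15/35 days reproducing the observed phenology
ordering) to 20 October.

* **Weather** is smooth and synthetic: per-colony wind regimes (mixtures of
  preferred blowing-toward directions drawn per 6-h block, blended
  spatially with Gaussian kernels of ~300 km around each colony over a
  slowly varying background flow, with mild diurnal modulation), a
  latitudinal-plus-diurnal temperature field, anti-phase humidity, synoptic
  pressure swings, episodic non-negative rain, and cloud fractions in
  (0, 1).
* **Birds** draw biometrics from sex- and colony-specific normals; the
  latent decision to migrate is Bernoulli with logit
  `1.9 + 1.2 · SMI_std` — better condition, higher migration probability,
  with the intercept chosen so the expected migrant fraction matches the
  observed ~80% after logistic-normal attenuation.
* **Departures** follow a discrete-time hazard at each eligible 2-h fix
  using the standardized coefficients intercept −4.97, tailwind 1.41,
  hours-after-sunset 4.37 and its quadratic −2.52, applied to covariates
  standardized with fixed within-simulation constants (tailwind scale
  15 km/h; hours centred at 1.5 h, scale 2.5 h). Tailwind is evaluated at
  the colony toward the bird's drawn destination. Under this hazard ~73% of
  departures ride positive tailwinds, which is the mechanism the analyses
  are meant to detect.
* **Flight** proceeds toward the destination at per-segment speed
  `72.05 − 10.73·male + 8.52·tailwind_std + 8.2·d_std − 8.79·d_std²`
  plus Gaussian noise (SD 8 km/h), with cumulative distance standardized
  (centre 300 km, scale 214.39 km) so the concave profile peaks at 400 km.
  Speeds are floored at 20 km/h — the package's declared minimum for a fix
  to count as flight — so every simulated migration satisfies the arrival
  rule it is later tested against. A quarter of migrants make one en-route
  stopover of 14–30 h.
* **Destinations** follow the qualitative colony-to-region pattern
  (Molentargius mostly south toward Tunisia; Comacchio mostly the nearby
  lagoon to the northeast; Margherita mostly north toward the Po Delta)
  with mixtures chosen so the direction-versus-wind analysis sees both an
  aligned and an anti-aligned colony. Minor destinations that would fall
  outside the simulated weather domain (longitude < 7.5° E) are replaced by
  within-domain stand-ins at comparable bearings and distances — a domain
  choice of the generator, stated here once.

All randomness comes from one master seed with per-module sub-streams
derived deterministically, so weather, birds and tracks are individually
reproducible and two runs with the same seed are byte-identical.

What the generator does **not** emulate: meteorologically realistic
reanalysis structure (fronts, terrain), flock or social dynamics (juveniles
following adults), tag failure and fix dropout, and real destination
geography beyond the qualitative pattern. Passing tests therefore show that
the estimators recover the generative structure under the study's design —
sample sizes, fix cadence, selection effects of the case-control window —
not that the field data would yield the same coefficients.

## Numerical choices and problem sizes

Convergence uses the fitting libraries' defaults with derivative
calculations disabled where they only serve post-hoc checks; singular
random-effect variances are reported as 0 with a boundary flag rather than
rejected. Ties at bin edges go to the right-closed convention stated above;
angles are normalized into [0, 360) before binning; 360° maps to 0°.

The test suite exercises: exact identities (wind decomposition over 10⁴
random inputs at < 1e-9; haversine against closed-form meridian/equator
arcs; sunset against an independently coded NOAA-spreadsheet oracle within
±3 min at the three colony coordinates), deterministic segmentation on 200
simulated tracks (100% strategy agreement with the generator's truth,
departure time within one fix interval), and stochastic recovery at
moderate scale: the departure GLMM refitted on 50 person-period replicates
of 200 birds (each 95% CI covering its generative coefficient in ≥ 90% of
replicates), and the speed LMM vertex recovered within [350, 450] km in
≥ 90% of 50 replicates of 30 birds × 30 segments. These sizes keep the
default suite comfortably under a coffee break on one core while leaving
the coverage claims statistically meaningful.

## Known limitations

* The case-control builder cannot reproduce the source's exact control-row
  count (which depends on the real tags' fix-time jitter); control counts
  here follow the declared inclusive window exactly.
* Published mean migratory speed differs between two sections of the source
  (54.6 vs 45.2 ± 1.6 km/h); the package reports its own mean and takes no
  side.
* With six observations per colony, the direction-versus-wind Poisson GLMs
  are reported exactly but should be read as descriptive.
* NetCDF I/O for weather grids is not provided; the long CSV dialect and
  in-memory/RDS paths cover the package's scales.
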