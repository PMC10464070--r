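## Body condition: Scaled Mass Index (SMI) and condition-dependent migration
## propensity.

#' Reference tarsus lengths for the Scaled Mass Index
#'
#' Defaults are the sex-specific mean tarsus of the sampled population:
#' 275 mm for males, 247 mm for females. `smi_reference_from_data()` recomputes
#' them from a biometrics table instead.
#'
#' @param male_mm,female_mm reference tarsus per sex (mm).
#' @return named list with `M` and `F` entries.
#' @export
smi_reference <- function(male_mm = 275, female_mm = 247) {
  list(M = male_mm, F = female_mm)
}

#' @rdname smi_reference
#' @param biometrics data.frame with `sex` ("F"/"M") and `tarsus_mm`.
#' @export
smi_reference_from_data <- function(biometrics) {
  smi_reference(male_mm = mean(biometrics$tarsus_mm[biometrics$sex == "M"]),
                female_mm = mean(biometrics$tarsus_mm[biometrics$sex == "F"]))
}

#' Scaled Mass Index
#'
#' Body mass standardized to a sex-specific reference tarsus. The default form
#' is `mass * (tarsus0 / tarsus)` (linear scaling exponent). The canonical
#' standardized-major-axis form `mass * (tarsus0 / tarsus)^b_SMA` is available
#' by supplying `sma_exponent` (estimate it with [smi_sma_exponent()]).
#'
#' @param mass_g body mass (g).
#' @param tarsus_mm tarsus length (mm), positive.
#' @param sex `"F"` or `"M"` (vectorized).
#' @param ref a [smi_reference()].
#' @param sma_exponent scaling exponent; 1 reproduces the linear form.
#' @return SMI in grams.
#' @export
scaled_mass_index <- function(mass_g, tarsus_mm, sex, ref = smi_reference(),
                              sma_exponent = 1) {
  if (any(tarsus_mm <= 0) || any(mass_g <= 0))
    stop_fledgr("mass and tarsus must be positive", "fledgr_invalid_input")
  if (!all(sex %in% c("F", "M")))
    stop_fledgr("unknown sex; no SMI reference available",
                "fledgr_missing_reference")
  t0 <- unlist(ref[sex], use.names = FALSE)
  mass_g * (t0 / tarsus_mm)^sma_exponent
}

#' Standardized-major-axis scaling exponent for the SMI
#'
#' Slope of the SMA regression of `log(mass)` on `log(tarsus)`:
#' `b_SMA = b_OLS / |r|`.
#'
#' @param mass_g,tarsus_mm positive numeric vectors.
#' @return the SMA exponent.
#' @export
smi_sma_exponent <- function(mass_g, tarsus_mm) {
  lx <- log(tarsus_mm); ly <- log(mass_g)
  r <- stats::cor(lx, ly)
  if (!is.finite(r) || abs(r) < 1e-12)
    stop_fledgr("mass and tarsus uncorrelated; SMA exponent undefined",
                "fledgr_invalid_input")
  stats::coef(stats::lm(ly ~ lx))[["lx"]] / abs(r)
}

#' Linear models for biometrics
#'
#' Gaussian LMs for each response (tarsus, mass, wing, SMI) as a function of
#' sex, colony, their interaction, and year. Single-level factors are dropped
#' with a note; aliased terms are reported, not fatal.
#'
#' @param biometrics data.frame with `sex`, `colony`, `year`, `tarsus_mm`,
#'   `mass_g`, `wing_mm` and optionally `smi_g` (computed when absent).
#' @param ref a [smi_reference()] used when `smi_g` is missing.
#' @return named list of [fledgr_fit] objects (one per response).
#' @export
fit_biometric_models <- function(biometrics, ref = smi_reference()) {
  b <- biometrics
  if (is.null(b$smi_g))
    b$smi_g <- scaled_mass_index(b$mass_g, b$tarsus_mm, b$sex, ref)
  b$sex <- factor(b$sex)
  b$colony <- factor(b$colony)
  b$year <- factor(b$year)
  terms <- c("sex", "colony", "year")
  keep <- terms[vapply(terms, function(v) nlevels(b[[v]]) > 1, logical(1))]
  rhs <- if (all(c("sex", "colony") %in% keep))
    paste(c("sex * colony", setdiff(keep, c("sex", "colony"))), collapse = " + ")
  else if (length(keep)) paste(keep, collapse = " + ") else "1"
  responses <- c(tarsus = "tarsus_mm", mass = "mass_g",
                 wing = "wing_mm", smi = "smi_g")
  out <- lapply(responses, function(y) {
    fit_lm(stats::as.formula(paste(y, "~", rhs)), data = b)
  })
  names(out) <- names(responses)
  out
}

#' Condition-dependent migration propensity
#'
#' Logistic regression of migration (0/1) on the Scaled Mass Index, with
#' McFadden's pseudo-R2. SMI is standardized so the slope is per SD.
#'
#' @param data data.frame with `migrate` (0/1) and `smi_g`.
#' @return a [fledgr_fit] with `mcfadden_r2` in its statistics.
#' @export
fit_propensity <- function(data) {
  if (length(unique(data$migrate)) < 2)
    stop_fledgr("both outcome classes required", "fledgr_invalid_input")
  fit_glm(migrate ~ smi_g, data = data, family = stats::binomial(),
          standardize = TRUE)
}
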