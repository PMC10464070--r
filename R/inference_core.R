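## Shared estimation machinery: predictor standardization, VIF screening,
## LM/GLM/LMM/GLMM fitting behind a single result contract, and the reported
## diagnostics (Wald type-III tables, McFadden R2, Nakagawa-style marginal R2,
## leave-one-predictor-out semi-partial R2, Pearson dispersion).
##
## Estimates are reported on the standardized-predictor scale (continuous
## predictors centred at the mean and scaled by the sample SD) unless
## standardization is turned off; the scaling record allows back-transform.

#' Centre and scale numeric columns
#'
#' Each selected column is centred at its mean and scaled by its sample SD.
#' Zero-variance columns are dropped with a warning.
#'
#' @param data data.frame (or numeric matrix).
#' @param cols columns to standardize; defaults to all numeric columns.
#' @return list: `data` (transformed), `center`, `scale` (named vectors),
#'   `dropped` (names of zero-variance columns).
#' @export
standardize_columns <- function(data, cols = NULL) {
  df <- as.data.frame(data)
  if (is.null(cols))
    cols <- names(df)[vapply(df, is.numeric, logical(1))]
  center <- scale <- stats::setNames(numeric(0), character(0))
  dropped <- character(0)
  for (cl in cols) {
    x <- df[[cl]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warn_fledgr(sprintf("zero-variance column '%s' dropped", cl),
                  "fledgr_zero_variance")
      df[[cl]] <- NULL
      dropped <- c(dropped, cl)
      next
    }
    m <- mean(x)
    df[[cl]] <- (x - m) / s
    center[cl] <- m
    scale[cl] <- s
  }
  list(data = df, center = center, scale = scale, dropped = dropped)
}

#' Variance-inflation-factor screening
#'
#' VIF of predictor j is `1 / (1 - R2_j)` from regressing column j on the
#' remaining columns. Predictors with VIF at or above the threshold are
#' removed iteratively (highest first, recomputing after each removal) until
#' all remaining VIFs are below it. Perfectly collinear columns are removed
#' first with an infinite-VIF flag.
#'
#' @param x numeric matrix or data.frame of predictors (>= 2 columns).
#' @param threshold removal threshold (default 3).
#' @return list: `retained` (column names), `removed`, `vif` (final VIF
#'   table), `history` (data.frame of removals).
#' @export
vif_screen <- function(x, threshold = 3) {
  x <- as.data.frame(x)
  if (ncol(x) < 2)
    stop_fledgr("need >= 2 predictors for VIF screening", "fledgr_invalid_input")
  vif_of <- function(df) {
    vapply(names(df), function(j) {
      r2 <- summary(stats::lm(df[[j]] ~ ., data = df[setdiff(names(df), j)]))$r.squared
      if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  removed <- character(0)
  hist <- list()
  while (ncol(x) >= 2) {
    v <- vif_of(x)
    if (all(v < threshold)) break
    worst <- names(v)[which.max(v)]
    hist[[length(hist) + 1]] <- data.frame(removed = worst, vif = v[[worst]])
    removed <- c(removed, worst)
    x[[worst]] <- NULL
  }
  final <- if (ncol(x) >= 2) vif_of(x) else stats::setNames(rep(1, ncol(x)), names(x))
  list(retained = names(x), removed = removed, vif = final,
       history = if (length(hist)) do.call(rbind, hist)
                 else data.frame(removed = character(0), vif = numeric(0)))
}

## --- fledgr_fit construction --------------------------------------------------

## term-block Wald type-III chi-square from coefficients and their covariance
.wald_type3 <- function(beta, V, assign, term_labels, has_intercept) {
  if (is.null(assign) || length(assign) != length(beta)) {
    ## rank-deficient fit dropped columns: fall back to 1-df blocks
    is_int <- names(beta) == "(Intercept)"
    assign <- cumsum(!is_int)
    assign[is_int] <- 0L
    term_labels <- names(beta)[!is_int]
  }
  terms_idx <- sort(unique(assign))
  rows <- lapply(terms_idx, function(a) {
    k <- which(assign == a)
    lab <- if (a == 0) "(Intercept)" else term_labels[a]
    b <- beta[k]
    Vi <- tryCatch(solve(V[k, k, drop = FALSE]), error = function(e) NULL)
    if (is.null(Vi))
      return(data.frame(term = lab, chisq = NA_real_, df = length(k), p = NA_real_))
    w <- as.numeric(t(b) %*% Vi %*% b)
    data.frame(term = lab, chisq = w, df = length(k),
               p = stats::pchisq(w, length(k), lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

.coef_table <- function(beta, se, df = NA_real_) {
  data.frame(term = names(beta), estimate = unname(beta), se = unname(se),
             ci_lo = unname(beta - 1.96 * se), ci_hi = unname(beta + 1.96 * se),
             statistic = unname(beta / se), df = df,
             p = 2 * stats::pnorm(-abs(unname(beta / se))),
             stringsAsFactors = FALSE)
}

## distribution-specific residual variance for the variance-partition R2
.dist_variance <- function(family, sigma2 = NULL, lambda_bar = NULL) {
  switch(family,
         gaussian = sigma2,
         binomial = pi^2 / 3,
         poisson = log(1 + 1 / lambda_bar))
}

## marginal R2 (fixed-effects variance partition, Nakagawa-style)
.marginal_r2 <- function(var_fixed, var_random, var_dist) {
  var_fixed / (var_fixed + var_random + var_dist)
}

new_fledgr_fit <- function(kind, model, family, formula, coef_table, wald,
                           stats_list, scaling = NULL, ranef_var = NULL,
                           notes = character(0), anova_table = NULL) {
  structure(list(kind = kind, model = model, family = family,
                 formula = formula, coef_table = coef_table,
                 wald_type3 = wald, stats = stats_list, scaling = scaling,
                 ranef_var = ranef_var, notes = notes,
                 anova_table = anova_table),
            class = "fledgr_fit")
}

## standardize continuous predictors appearing in a formula
.standardize_for_formula <- function(formula, data, extra_skip = character(0)) {
  vars <- all.vars(formula)
  resp <- all.vars(formula[[2]])
  bars <- lme4::findbars(formula)
  group_vars <- unlist(lapply(bars, function(b) all.vars(b[[3]])))
  cand <- setdiff(vars, c(resp, group_vars, extra_skip))
  cand <- cand[vapply(cand, function(v)
    is.numeric(data[[v]]) && length(unique(data[[v]])) > 2, logical(1))]
  if (!length(cand))
    return(list(data = data, center = numeric(0), scale = numeric(0)))
  st <- withCallingHandlers(
    standardize_columns(data[cand]),
    fledgr_zero_variance = function(w) invokeRestart("muffleWarning"))
  for (v in names(st$center)) data[[v]] <- st$data[[v]]
  list(data = data, center = st$center, scale = st$scale,
       dropped = st$dropped)
}

## --- LM / GLM -----------------------------------------------------------------

#' Fit a linear model under the package's result contract
#'
#' @param formula model formula (quadratics as `I(x^2)` on the standardized
#'   variable).
#' @param data data.frame.
#' @param standardize centre/scale continuous predictors first (default TRUE).
#' @param semipartial also compute leave-one-predictor-out semi-partial R2
#'   (requires refits; default FALSE).
#' @return a `fledgr_fit`.
#' @export
fit_lm <- function(formula, data, standardize = TRUE, semipartial = FALSE) {
  st <- if (standardize) .standardize_for_formula(formula, data)
        else list(data = data, center = numeric(0), scale = numeric(0))
  m <- stats::lm(formula, data = st$data)
  sm <- summary(m)
  beta <- stats::coef(m)
  aliased <- is.na(beta)
  notes <- if (any(aliased))
    sprintf("aliased terms: %s", paste(names(beta)[aliased], collapse = ", "))
  else character(0)
  keep <- !aliased
  V <- stats::vcov(m)
  nm <- names(beta)[keep]
  V <- V[nm, nm, drop = FALSE]
  se <- sqrt(diag(V))
  ct <- .coef_table(beta[keep], se, df = m$df.residual)
  ct$p <- 2 * stats::pt(-abs(ct$statistic), m$df.residual)
  asgn <- attr(stats::model.matrix(m), "assign")[keep]
  wald <- .wald_type3(beta[keep], V, asgn,
                      attr(stats::terms(m), "term.labels"), TRUE)
  var_f <- stats::var(as.numeric(stats::model.matrix(m)[, keep, drop = FALSE] %*% beta[keep]))
  sigma2 <- sm$sigma^2
  stats_list <- list(loglik = as.numeric(stats::logLik(m)),
                     r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                     marginal_r2 = .marginal_r2(var_f, 0, sigma2),
                     n = stats::nobs(m))
  fit <- new_fledgr_fit("lm", m, "gaussian", formula, ct, wald, stats_list,
                        scaling = st[c("center", "scale")], notes = notes)
  if (semipartial) fit$stats$semipartial_r2 <- semipartial_r2(fit)
  fit
}

#' Fit a GLM (binomial logit or Poisson log) under the result contract
#'
#' Poisson fits carry a Pearson dispersion statistic (chi-square / df);
#' binomial fits carry McFadden's R2 and a complete-separation flag.
#'
#' @inheritParams fit_lm
#' @param family a `stats::family` (binomial or poisson).
#' @return a `fledgr_fit`.
#' @export
fit_glm <- function(formula, data, family, standardize = TRUE,
                    semipartial = FALSE) {
  st <- if (standardize) .standardize_for_formula(formula, data)
        else list(data = data, center = numeric(0), scale = numeric(0))
  m <- stats::glm(formula, data = st$data, family = family)
  if (!m$converged)
    stop_fledgr("GLM did not converge", "fledgr_no_convergence")
  fam <- family$family
  beta <- stats::coef(m)
  keep <- !is.na(beta)
  V <- stats::vcov(m)
  nm <- names(beta)[keep]
  V <- V[nm, nm, drop = FALSE]
  se <- sqrt(diag(V))
  ct <- .coef_table(beta[keep], se)
  asgn <- attr(stats::model.matrix(m), "assign")[keep]
  wald <- .wald_type3(beta[keep], V, asgn,
                      attr(stats::terms(m), "term.labels"), TRUE)
  notes <- character(0)
  ll <- as.numeric(stats::logLik(m))
  null_ll <- as.numeric(stats::logLik(
    stats::glm(stats::update(formula, . ~ 1), data = st$data, family = family)))
  mcfadden <- if (abs(null_ll) < 1e-12) 0 else 1 - ll / null_ll
  mu <- stats::fitted(m)
  pearson <- sum(stats::residuals(m, type = "pearson")^2)
  disp <- pearson / m$df.residual
  if (fam == "binomial") {
    if (any(mu > 1 - 1e-8 | mu < 1e-8) && any(abs(beta[keep]) > 10)) {
      notes <- c(notes, paste("possible complete separation: estimates on the",
                              "boundary; consider a penalized refit"))
    }
  }
  var_f <- stats::var(as.numeric(stats::model.matrix(m)[, keep, drop = FALSE] %*% beta[keep]))
  vd <- .dist_variance(fam, sigma2 = disp, lambda_bar = mean(mu))
  stats_list <- list(loglik = ll, mcfadden_r2 = mcfadden,
                     marginal_r2 = .marginal_r2(var_f, 0, vd),
                     dispersion = disp, n = stats::nobs(m))
  fit <- new_fledgr_fit("glm", m, fam, formula, ct, wald, stats_list,
                        scaling = st[c("center", "scale")], notes = notes)
  if (semipartial) fit$stats$semipartial_r2 <- semipartial_r2(fit)
  fit
}

## --- LMM / GLMM ---------------------------------------------------------------

#' Fit a Gaussian random-intercept mixed model
#'
#' REML fit with per-term F tests using the Satterthwaite degree-of-freedom
#' approximation (Kenward-Roger on request, when the support package is
#' available). A singular random-effect variance is reported as 0 with a
#' boundary flag.
#'
#' @inheritParams fit_lm
#' @param ddf denominator-df approximation, `"Satterthwaite"` or
#'   `"Kenward-Roger"`.
#' @return a `fledgr_fit` with `ranef_var` and an `anova_table`.
#' @export
fit_lmm <- function(formula, data, standardize = TRUE,
                    ddf = c("Satterthwaite", "Kenward-Roger"),
                    semipartial = FALSE) {
  ddf <- match.arg(ddf)
  st <- if (standardize) .standardize_for_formula(formula, data)
        else list(data = data, center = numeric(0), scale = numeric(0))
  m <- lmerTest::lmer(formula, data = st$data, REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
  notes <- character(0)
  if (lme4::isSingular(m, tol = 1e-5))
    notes <- c(notes, "random-effect variance at boundary (reported as 0)")
  beta <- lme4::fixef(m)
  V <- as.matrix(stats::vcov(m))
  se <- sqrt(diag(V))
  ct <- .coef_table(beta, se)
  X <- stats::model.matrix(m)
  asgn <- attr(X, "assign")
  wald <- .wald_type3(beta, V, asgn, attr(stats::terms(m), "term.labels"), TRUE)
  an <- tryCatch(as.data.frame(stats::anova(m, ddf = ddf)),
                 error = function(e) NULL)
  if (is.null(an) && ddf == "Kenward-Roger") {
    notes <- c(notes, "Kenward-Roger unavailable; Satterthwaite used")
    an <- as.data.frame(stats::anova(m, ddf = "Satterthwaite"))
  }
  vc <- as.data.frame(lme4::VarCorr(m))
  re_var <- sum(vc$vcov[vc$grp != "Residual"])
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  var_f <- stats::var(as.numeric(X %*% beta))
  stats_list <- list(loglik = as.numeric(stats::logLik(m)),
                     loglik_reml = as.numeric(stats::logLik(m, REML = TRUE)),
                     marginal_r2 = .marginal_r2(var_f, re_var, sigma2),
                     n = stats::nobs(m))
  fit <- new_fledgr_fit("lmm", m, "gaussian", formula, ct, wald, stats_list,
                        scaling = st[c("center", "scale")],
                        ranef_var = re_var, notes = notes, anova_table = an)
  if (semipartial) fit$stats$semipartial_r2 <- semipartial_r2(fit)
  fit
}

#' Fit a binomial-logit random-intercept GLMM
#'
#' Laplace approximation to the marginal likelihood by default; adaptive
#' Gauss-Hermite quadrature via `nAGQ`. Wald type-III chi-square tests per
#' term. Complete separation or non-convergence raises an explicit error.
#'
#' @inheritParams fit_lm
#' @param nAGQ number of adaptive quadrature points (1 = Laplace).
#' @return a `fledgr_fit`.
#' @export
fit_glmm_binomial <- function(formula, data, standardize = TRUE, nAGQ = 1,
                              semipartial = FALSE) {
  st <- if (standardize) .standardize_for_formula(formula, data)
        else list(data = data, center = numeric(0), scale = numeric(0))
  resp <- all.vars(formula[[2]])
  if (length(unique(st$data[[resp]])) < 2)
    stop_fledgr("response has a single class (separation-degenerate)",
                "fledgr_separation")
  m <- lme4::glmer(formula, data = st$data, family = stats::binomial(),
                   nAGQ = nAGQ,
                   control = lme4::glmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  conv <- m@optinfo$conv$opt
  if (!is.null(conv) && conv != 0)
    stop_fledgr("GLMM optimizer reported non-convergence",
                "fledgr_no_convergence")
  notes <- character(0)
  if (lme4::isSingular(m, tol = 1e-5))
    notes <- c(notes, "random-effect variance at boundary (reported as 0)")
  beta <- lme4::fixef(m)
  if (any(abs(beta) > 15))
    notes <- c(notes, "very large coefficient(s): possible separation")
  V <- as.matrix(stats::vcov(m))
  se <- sqrt(diag(V))
  ct <- .coef_table(beta, se)
  X <- stats::model.matrix(m)
  asgn <- attr(X, "assign")
  wald <- .wald_type3(beta, V, asgn, attr(stats::terms(m), "term.labels"), TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  re_var <- sum(vc$vcov)
  ll <- as.numeric(stats::logLik(m))
  null_form <- stats::as.formula(
    paste(resp, "~ 1 +", paste(vapply(lme4::findbars(formula),
                                      function(b) paste0("(", deparse(b), ")"),
                                      character(1)), collapse = " + ")))
  null_ll <- as.numeric(stats::logLik(
    lme4::glmer(null_form, data = st$data, family = stats::binomial(),
                nAGQ = nAGQ,
                control = lme4::glmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))))
  var_f <- stats::var(as.numeric(X %*% beta))
  stats_list <- list(loglik = ll,
                     mcfadden_r2 = if (abs(null_ll) < 1e-12) 0 else 1 - ll / null_ll,
                     marginal_r2 = .marginal_r2(var_f, re_var, pi^2 / 3),
                     n = stats::nobs(m))
  fit <- new_fledgr_fit("glmm", m, "binomial", formula, ct, wald, stats_list,
                        scaling = st[c("center", "scale")],
                        ranef_var = re_var, notes = notes)
  if (semipartial) fit$stats$semipartial_r2 <- semipartial_r2(fit)
  fit
}

## --- diagnostics --------------------------------------------------------------

#' Leave-one-predictor-out semi-partial R2
#'
#' For each fixed-effect term, the drop in fixed-effects (marginal) R2 when
#' the model is refitted without that term. A deterministic, declared
#' definition of predictor importance.
#'
#' @param fit a `fledgr_fit`.
#' @return named numeric vector, one entry per droppable term.
#' @export
semipartial_r2 <- function(fit) {
  labs <- fit$wald_type3$term
  labs <- setdiff(labs, "(Intercept)")
  full <- fit$stats$marginal_r2
  out <- stats::setNames(numeric(0), character(0))
  for (lb in labs) {
    f2 <- stats::as.formula(paste(". ~ . -", lb))
    reduced <- tryCatch({
      switch(fit$kind,
        lm = fit_lm(stats::update(fit$formula, f2),
                    data = stats::model.frame(fit$model), standardize = FALSE),
        glm = fit_glm(stats::update(fit$formula, f2),
                      data = stats::model.frame(fit$model),
                      family = stats::family(fit$model), standardize = FALSE),
        lmm = fit_lmm(stats::update(fit$formula, f2),
                      data = fit$model@frame, standardize = FALSE),
        glmm = fit_glmm_binomial(stats::update(fit$formula, f2),
                                 data = fit$model@frame, standardize = FALSE))
    }, error = function(e) NULL)
    out[lb] <- if (is.null(reduced)) NA_real_
               else max(0, full - reduced$stats$marginal_r2)
  }
  out
}

## --- methods ------------------------------------------------------------------

#' @export
print.fledgr_fit <- function(x, ...) {
  cat(sprintf("<fledgr_fit:%s> %s (%s), n = %d\n", x$kind,
              deparse(x$formula), x$family, x$stats$n))
  ct <- x$coef_table
  ct[-1] <- lapply(ct[-1], function(v) signif(v, 4))
  print(ct, row.names = FALSE)
  if (!is.null(x$ranef_var))
    cat(sprintf("random-intercept variance: %.4g\n", x$ranef_var))
  for (nm in c("mcfadden_r2", "marginal_r2", "dispersion"))
    if (!is.null(x$stats[[nm]]))
      cat(sprintf("%s: %.3f\n", nm, x$stats[[nm]]))
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.fledgr_fit <- function(object, ...) {
  print(object)
  cat("\nWald type-III tests:\n")
  w <- object$wald_type3
  w[-1] <- lapply(w[-1], function(v) signif(v, 4))
  print(w, row.names = FALSE)
  invisible(object)
}

#' @export
coef.fledgr_fit <- function(object, ...) {
  stats::setNames(object$coef_table$estimate, object$coef_table$term)
}

#' @export
confint.fledgr_fit <- function(object, parm, level = 0.95, ...) {
  ct <- object$coef_table
  out <- cbind(ct$ci_lo, ct$ci_hi)
  rownames(out) <- ct$term
  colnames(out) <- c("2.5 %", "97.5 %")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
as.data.frame.fledgr_fit <- function(x, ...) x$coef_table

#' Write a fit's coefficient table as tidy CSV
#'
#' Columns `term, estimate, se, ci_lo, ci_hi, statistic, df, p`.
#'
#' @param fit a `fledgr_fit`.
#' @param path output CSV.
#' @export
write_fit_csv <- function(fit, path) {
  utils::write.csv(format(fit$coef_table, digits = 10), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
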