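#' Prepare the trait-model design table
#'
#' Applies the transformation and scaling conventions of the trait models:
#' branch age is natural-log transformed, the vulnerability-curve slope
#' (when present as a response) is natural-log transformed, and every
#' numeric predictor is centred to mean 0 and scaled to SD 1 within the
#' modelled dataset. Scaling constants are stored so per-SD coefficients
#' can be mapped back to the raw predictor scale.
#'
#' @param table Trait table with one row per tree: predictors `cwb`,
#'   `awc`, `height`, `branch_age`, `ci`; grouping `site_id`; any of the
#'   responses `p12`, `p50`, `p88`, `slope`, `ks`.
#' @return List with `frame` (tibble: `site_id`, scaled predictors
#'   `cwb_z`, `awc_z`, `height_z`, `log_age_z`, `ci_z`, responses incl.
#'   `log_slope` if `slope` present, `n_dropped` rows removed listwise)
#'   and `scaling` (tibble of centre/scale per predictor).
#' @export
prepare_model_frame <- function(table) {
  preds_raw <- c("cwb", "awc", "height", "branch_age", "ci")
  miss <- setdiff(c(preds_raw, "site_id"), names(table))
  if (length(miss))
    stopf("prepare_model_frame(): missing columns: %s",
          paste(miss, collapse = ", "))
  responses <- intersect(c("p12", "p50", "p88", "slope", "ks"), names(table))

  used <- table[, c("site_id", preds_raw, responses), drop = FALSE]
  cc <- stats::complete.cases(used)
  n_dropped <- sum(!cc)
  used <- used[cc, , drop = FALSE]

  if (any(used$branch_age <= 0))
    stopf("prepare_model_frame(): branch_age must be > 0 for the log transform")
  if ("slope" %in% responses && any(used$slope <= 0))
    stopf("prepare_model_frame(): slope must be > 0 for the log transform")

  raw <- list(cwb = used$cwb, awc = used$awc, height = used$height,
              log_age = log(used$branch_age), ci = used$ci)
  centre <- vapply(raw, mean, numeric(1))
  scale <- vapply(raw, sd, numeric(1))
  zero <- names(scale)[!is.finite(scale) | scale == 0]
  if (length(zero))
    stopf("prepare_model_frame(): zero-variance predictor(s): %s",
          paste(zero, collapse = ", "))

  frame <- tibble::tibble(site_id = factor(used$site_id))
  for (p in names(raw))
    frame[[paste0(p, "_z")]] <- (raw[[p]] - centre[[p]]) / scale[[p]]
  for (r in responses) frame[[r]] <- used[[r]]
  if ("slope" %in% responses) frame$log_slope <- log(used$slope)

  list(frame = frame,
       scaling = tibble::tibble(predictor = names(raw),
                                centre = unname(centre),
                                scale = unname(scale)),
       n_dropped = n_dropped)
}

#' Map a per-SD coefficient back to the raw predictor scale
#'
#' @param estimate Coefficient on the standardised (per-SD) scale.
#' @param predictor Predictor name as in the scaling record.
#' @param scaling The `scaling` tibble from [prepare_model_frame()].
#' @return Coefficient per raw predictor unit.
#' @export
unscale_coefficient <- function(estimate, predictor, scaling) {
  i <- match(predictor, scaling$predictor)
  if (is.na(i)) stopf("unscale_coefficient(): unknown predictor %s", predictor)
  estimate / scaling$scale[i]
}

lmm_predictors <- c("cwb_z", "awc_z", "height_z", "log_age_z", "ci_z")

#' Fit one random-intercept trait model
#'
#' REML linear mixed-effects model for one hydraulic trait:
#' fixed effects for the five standardised predictors and a random
#' intercept per site. Inference per coefficient is by Wald t tests with
#' Satterthwaite's approximation to the degrees of freedom. Marginal and
#' conditional R2 follow the Nakagawa variance decomposition, and the
#' same three variance components are reported as fractions. A singular
#' fit (site variance collapsing to zero) is flagged, not an error.
#'
#' @param frame Prepared design tibble from [prepare_model_frame()].
#' @param response Name of the response column (e.g. `"p50"`,
#'   `"log_slope"`).
#' @return An `lmm_result`: `response`, `coefficients` (tibble: term,
#'   estimate, se, df, t, p), `site_sd`, `residual_sd`, `marginal_r2`,
#'   `conditional_r2`, `variance_fractions` (fixed, site, residual),
#'   `singular`, `n`, `n_sites`, and the underlying `fit`.
#' @export
fit_lmm <- function(frame, response) {
  if (!response %in% names(frame))
    stopf("fit_lmm(): response `%s` not in frame", response)
  miss <- setdiff(c(lmm_predictors, "site_id"), names(frame))
  if (length(miss))
    stopf("fit_lmm(): frame lacks columns: %s", paste(miss, collapse = ", "))
  if (length(unique(frame$site_id)) < 2L)
    stopf("fit_lmm(): need >= 2 sites for a random intercept")

  form <- stats::as.formula(paste(
    response, "~", paste(lmm_predictors, collapse = " + "), "+ (1 | site_id)"))
  fit <- lmerTest::lmer(form, data = frame, REML = TRUE)

  smr <- summary(fit, ddf = "Satterthwaite")$coefficients
  coefs <- tibble::tibble(
    term = rownames(smr),
    estimate = unname(smr[, "Estimate"]), se = unname(smr[, "Std. Error"]),
    df = unname(smr[, "df"]), t = unname(smr[, "t value"]),
    p = unname(smr[, "Pr(>|t|)"]))

  vc <- as.data.frame(lme4::VarCorr(fit))
  site_sd <- vc$sdcor[vc$grp == "site_id"]
  resid_sd <- vc$sdcor[vc$grp == "Residual"]

  # Nakagawa decomposition: variance of the fixed-effect linear predictor
  # against the two estimated variance components
  X <- stats::model.matrix(fit)
  var_fixed <- var(as.numeric(X %*% lme4::fixef(fit)))
  tot <- var_fixed + site_sd^2 + resid_sd^2
  if (tot <= 0) stopf("fit_lmm(): total variance is zero; R2 undefined")
  marginal <- var_fixed / tot
  conditional <- (var_fixed + site_sd^2) / tot
  fractions <- c(fixed = var_fixed / tot, site = site_sd^2 / tot,
                 residual = resid_sd^2 / tot)

  structure(list(
    response = response, coefficients = coefs,
    site_sd = site_sd, residual_sd = resid_sd,
    marginal_r2 = marginal, conditional_r2 = conditional,
    variance_fractions = fractions,
    singular = lme4::isSingular(fit),
    n = stats::nobs(fit), n_sites = length(unique(frame$site_id)),
    fit = fit), class = "lmm_result")
}

#' @method print lmm_result
#' @export
print.lmm_result <- function(x, digits = 3, ...) {
  cat(sprintf("Random-intercept trait model: %s (n = %d, %d sites%s)\n",
              x$response, x$n, x$n_sites,
              if (x$singular) ", singular fit" else ""))
  print(as.data.frame(x$coefficients), digits = digits, row.names = FALSE)
  cat(sprintf("  site SD %.3f, residual SD %.3f\n", x$site_sd, x$residual_sd))
  cat(sprintf("  marginal R2 %.3f, conditional R2 %.3f\n",
              x$marginal_r2, x$conditional_r2))
  cat(sprintf("  variance fractions: fixed %.2f, site %.2f, residual %.2f\n",
              x$variance_fractions["fixed"], x$variance_fractions["site"],
              x$variance_fractions["residual"]))
  invisible(x)
}

#' Wald t tests for a fitted trait model
#'
#' Per-coefficient t statistics (estimate / SE), Satterthwaite degrees of
#' freedom and two-sided p-values, as extracted from the REML fit.
#'
#' @param result An `lmm_result` from [fit_lmm()].
#' @return Tibble with `term`, `estimate`, `se`, `df`, `t`, `p`.
#' @export
wald_t_tests <- function(result) {
  stopifnot(inherits(result, "lmm_result"))
  if (any(!is.finite(result$coefficients$se) | result$coefficients$se == 0))
    stopf("wald_t_tests(): zero or non-finite standard error")
  result$coefficients
}

#' Nakagawa marginal and conditional R-squared
#'
#' @param result An `lmm_result` from [fit_lmm()].
#' @return Named vector `c(marginal, conditional)`.
#' @export
nakagawa_r2 <- function(result) {
  stopifnot(inherits(result, "lmm_result"))
  c(marginal = result$marginal_r2, conditional = result$conditional_r2)
}

#' Variance fractions of a fitted trait model
#'
#' The shares of fixed-effect, between-site and residual variance in the
#' Nakagawa total; they sum to one, the fixed share equals the marginal R2
#' and the site share equals conditional minus marginal R2.
#'
#' @param result An `lmm_result` from [fit_lmm()].
#' @return Named vector `c(fixed, site, residual)`.
#' @export
variance_fractions <- function(result) {
  stopifnot(inherits(result, "lmm_result"))
  result$variance_fractions
}

#' Fit the five standard trait models
#'
#' Fits the random-intercept model independently for each available
#' response — P12, P50, P88, log slope, Ks — on one prepared frame. No
#' multiple-testing correction is applied across the five models.
#'
#' @param table Raw trait table (see [prepare_model_frame()]).
#' @return List with `models` (named list of `lmm_result`), `scaling`,
#'   `n_dropped`.
#' @export
fit_trait_models <- function(table) {
  prep <- prepare_model_frame(table)
  responses <- intersect(c("p12", "p50", "p88", "log_slope", "ks"),
                         names(prep$frame))
  models <- lapply(responses, function(r) fit_lmm(prep$frame, r))
  names(models) <- responses
  list(models = models, scaling = prep$scaling, n_dropped = prep$n_dropped)
}

#' Pairwise correlation screen for collinearity
#'
#' Pearson correlations between every pair of predictor columns, with a
#' flag for any pair at or above the collinearity threshold.
#'
#' @param table Data frame of predictors (numeric columns used as given).
#' @param threshold Absolute correlation at which a pair is flagged.
#' @param columns Columns to screen (default: all numeric columns).
#' @return List with `correlations` (matrix), `flagged` (tibble of pairs
#'   with `|r| >= threshold`), `threshold`.
#' @export
correlation_screen <- function(table, threshold = 0.7, columns = NULL) {
  if (is.null(columns))
    columns <- names(table)[vapply(table, is.numeric, logical(1))]
  if (nrow(table) < 3L)
    stopf("correlation_screen(): need >= 3 rows")
  x <- as.data.frame(table[, columns, drop = FALSE])
  constant <- columns[vapply(x, function(v) sd(v) == 0 || !is.finite(sd(v)),
                             logical(1))]
  if (length(constant))
    stopf("correlation_screen(): constant column(s): %s",
          paste(constant, collapse = ", "))
  r <- stats::cor(x, method = "pearson")
  pairs <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
  flagged <- tibble::tibble(
    var1 = rownames(r)[pairs[, 1L]], var2 = colnames(r)[pairs[, 2L]],
    r = r[pairs])
  list(correlations = r, flagged = flagged, threshold = threshold)
}
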