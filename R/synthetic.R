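#' Configuration of a synthetic hydraulic-trait study
#'
#' Defines the hierarchical study design (sites x trees, one measured
#' branch per tree) and the generating values for traits and covariates.
#' Defaults emulate a 30-site x 10-tree field campaign on sandy lowland
#' soils: fixed-effect sizes are on the per-standard-deviation scale of the
#' predictors, and the generating values for the three primary traits
#' (P50, log slope, Ks) are the mixed-model estimates of that design
#' (P50 intercept -3.381 MPa, site SD 0.199, residual SD 0.279, etc.).
#'
#' @param n_sites Number of sites, >= 1.
#' @param n_trees_per_site Number of sampled trees per site, >= 1.
#' @param seed Integer seed governing every random draw.
#' @param intercepts Named vector of trait intercepts: `p50` (MPa),
#'   `log_slope` (log MPa^-1), `ks` (kg m^-1 MPa^-1 s^-1).
#' @param fixed_effects Named list (per trait) of named per-SD effect
#'   sizes for predictors `cwb`, `awc`, `height`, `log_age`, `ci`.
#' @param site_sd,residual_sd Named vectors of between-site and residual
#'   SDs per trait; `site_sd >= 0`, `residual_sd > 0`.
#' @param covariate_ranges Named list of `(min, max)` ranges for `cwb`
#'   (mm month^-1), `awc` (mm), `map` (mm yr^-1), `mat` (degC), `dbh`
#'   (cm), `height` (m).
#' @param branch_age_range,branch_age_mean Range (years) and target mean of
#'   the shifted-lognormal branch-age distribution.
#' @param noise_cv Cavitron measurement noise as a fraction of Kmax, >= 0.
#' @param pressure_step Pressure increment of the cavitron schedule, MPa,
#'   negative.
#' @param start_pressure First cavitron pressure, MPa, negative.
#' @param years Calendar years of the generated climate record.
#' @return A `study_config` list, validated.
#' @export
study_config <- function(
    n_sites = 30L,
    n_trees_per_site = 10L,
    seed = 1L,
    intercepts = c(p50 = -3.381, log_slope = 1.049, ks = 1.536),
    fixed_effects = list(
      p50 = c(cwb = 0.004, awc = 0.086, height = 0.000,
              log_age = 0.088, ci = -0.011),
      log_slope = c(cwb = -0.040, awc = 0.000, height = -0.024,
                    log_age = 0.015, ci = 0.016),
      ks = c(cwb = 0.026, awc = 0.046, height = 0.009,
             log_age = -0.048, ci = 0.022)),
    site_sd = c(p50 = 0.199, log_slope = 0.118, ks = 0.175),
    residual_sd = c(p50 = 0.279, log_slope = 0.258, ks = 0.535),
    covariate_ranges = list(
      cwb = c(-10.8, 25.5), awc = c(43.4, 301.0), map = c(522, 886),
      mat = c(9.0, 10.0), dbh = c(36, 58), height = c(21, 34)),
    branch_age_range = c(1.5, 20.5),
    branch_age_mean = 6.0,
    noise_cv = 0.05,
    pressure_step = -0.25,
    start_pressure = -0.37,
    years = 1991:2018) {
  if (n_sites < 1 || n_trees_per_site < 1)
    stopf("study_config(): n_sites and n_trees_per_site must be >= 1")
  traits <- c("p50", "log_slope", "ks")
  preds <- c("cwb", "awc", "height", "log_age", "ci")
  if (!all(traits %in% names(intercepts)))
    stopf("study_config(): intercepts must name %s",
          paste(traits, collapse = ", "))
  for (t in traits) {
    if (!all(preds %in% names(fixed_effects[[t]])))
      stopf("study_config(): fixed_effects$%s must name %s", t,
            paste(preds, collapse = ", "))
    if (site_sd[[t]] < 0) stopf("study_config(): site_sd must be >= 0")
    if (residual_sd[[t]] <= 0) stopf("study_config(): residual_sd must be > 0")
  }
  for (nm in names(covariate_ranges)) {
    r <- covariate_ranges[[nm]]
    if (length(r) != 2L || r[1L] > r[2L])
      stopf("study_config(): covariate range `%s` has min > max", nm)
  }
  if (noise_cv < 0) stopf("study_config(): noise_cv must be >= 0")
  if (pressure_step >= 0)
    stopf("study_config(): pressure_step must be negative (MPa)")
  if (start_pressure >= 0)
    stopf("study_config(): start_pressure must be negative (MPa)")
  structure(list(
    n_sites = as.integer(n_sites),
    n_trees_per_site = as.integer(n_trees_per_site),
    seed = as.integer(seed), intercepts = intercepts,
    fixed_effects = fixed_effects, site_sd = site_sd,
    residual_sd = residual_sd, covariate_ranges = covariate_ranges,
    branch_age_range = branch_age_range, branch_age_mean = branch_age_mean,
    noise_cv = noise_cv, pressure_step = pressure_step,
    start_pressure = start_pressure, years = years),
    class = "study_config")
}

runif_range <- function(n, range) runif(n, range[1L], range[2L])

# Truncated normal by inverse-CDF sampling (exact, no rejection loop).
rtnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

# Shifted lognormal branch ages: age = shift + X, X lognormal with
# E[X] = target mean - shift; upper tail beyond the range resampled.
r_branch_age <- function(n, range, mean_age, sdlog = 0.75) {
  shift <- range[1L]
  meanlog <- log(mean_age - shift) - sdlog^2 / 2
  out <- shift + rlnorm(n, meanlog, sdlog)
  bad <- out > range[2L]
  while (any(bad)) {
    out[bad] <- shift + rlnorm(sum(bad), meanlog, sdlog)
    bad <- out > range[2L]
  }
  out
}

# Deterministic seasonal climate: cosine annual cycles whose deviations sum
# exactly to zero over 12 months, so annual aggregates equal the configured
# site values to floating point.
site_monthly_climate <- function(site_id, map, mat, cwb, years) {
  grid <- expand.grid(month = 1:12, year = years)
  seas <- cos(2 * pi * (grid$month - 7) / 12)
  precip <- map / 12 + 8 * seas
  pet <- map / 12 - cwb + 16 * seas
  temp <- mat + 8.5 * seas
  tibble::tibble(site_id = site_id, year = grid$year, month = grid$month,
                 precip_mm = precip, pet_mm = pmax(pet, 0), temp_C = temp)
}

#' Simulate study covariates, stand geometry, soil and climate
#'
#' Draws the site-level water-availability covariates (CWB, AWC, MAP, MAT)
#' uniformly within the configured ranges, places each site's stand on a
#' jittered grid (sampled trees plus enough neighbour trees that every
#' sampled tree has at least three competitors), draws tree DBH and height,
#' branch ring counts and diameters from a right-skewed age distribution,
#' and generates matching monthly climate records and sandy three-layer
#' soil profiles.
#'
#' @param config A [study_config()].
#' @return A `synthetic_study` list with `site_table`, `tree_table`
#'   (sampled trees), `stand_table` (all mapped trees incl. neighbours),
#'   `branch_table`, `soil_table`, `climate_table`, and the `config`.
#'   Trait columns are added later by [simulate_true_traits()].
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cr <- config$covariate_ranges
  ns <- config$n_sites
  nt <- config$n_trees_per_site

  with_seed(child_seed(config$seed, "covariates"), {
    site_id <- sprintf("S%02d", seq_len(ns))
    site_table <- tibble::tibble(
      site_id = site_id,
      cwb = runif_range(ns, cr$cwb),
      awc = runif_range(ns, cr$awc),
      map = runif_range(ns, cr$map),
      mat = runif_range(ns, cr$mat))

    climate_table <- do.call(rbind, lapply(seq_len(ns), function(i)
      site_monthly_climate(site_id[i], site_table$map[i], site_table$mat[i],
                           site_table$cwb[i], config$years)))

    # stand maps: jittered grid; spacing varies between sites so that
    # Hegyi index site means span the realistic 0.4-0.7 range
    stand_rows <- lapply(seq_len(ns), function(i) {
      n_stand <- max(nt + 15L, 25L)
      side <- ceiling(sqrt(n_stand))
      spacing <- runif(1, 4.5, 8)
      gx <- rep(seq_len(side), side)[seq_len(n_stand)]
      gy <- rep(seq_len(side), each = side)[seq_len(n_stand)]
      x <- gx * spacing + runif(n_stand, -1.5, 1.5)
      y <- gy * spacing + runif(n_stand, -1.5, 1.5)
      ht_mean <- runif(1, cr$height[1L] + 2.5, cr$height[2L] - 2.5)
      sampled <- sample.int(n_stand, nt)
      tibble::tibble(
        tree_id = sprintf("%s_T%02d", site_id[i], seq_len(n_stand)),
        site_id = site_id[i],
        dbh = rtnorm(n_stand, 46, 4.5, cr$dbh[1L], cr$dbh[2L]),
        height = rtnorm(n_stand, ht_mean, 1.2, cr$height[1L], cr$height[2L]),
        x = x, y = y,
        is_sample = seq_len(n_stand) %in% sampled)
    })
    stand_table <- do.call(rbind, stand_rows)
    tree_table <- stand_table[stand_table$is_sample, , drop = FALSE]
    tree_table$is_sample <- NULL

    # one measured branch per sampled tree
    nb <- nrow(tree_table)
    age <- r_branch_age(nb, config$branch_age_range, config$branch_age_mean)
    total_rings <- pmax(round(2 * age), 3)
    delta <- pmin(stats::rpois(nb, 1.5), total_rings - 2L)
    rings_acr <- pmax(1L, as.integer(floor((total_rings - delta) / 2)))
    rings_bas <- as.integer(total_rings - rings_acr)
    dia_bas <- rtnorm(nb, 8.97, 1.0, 6.5, 11.5)
    branch_table <- tibble::tibble(
      branch_id = sprintf("%s_B", tree_table$tree_id),
      tree_id = tree_table$tree_id,
      basipetal_diameter_mm = dia_bas,
      acropetal_diameter_mm = dia_bas - runif(nb, 0.3, 1.2),
      segment_length_cm = 27.5,
      rings_basipetal = rings_bas,
      rings_acropetal = rings_acr,
      flushed = TRUE,
      max_kh = NA_real_)

    # sandy pleistocene-style soil profiles, three layers to 60 cm
    soil_rows <- lapply(seq_len(ns), function(i) {
      sand0 <- runif(1, 0.55, 0.90)
      clay0 <- runif(1, 0.02, 0.10)
      lay <- data.frame(top_cm = c(0, 10, 30), bottom_cm = c(10, 30, 60))
      sand <- pmin(pmax(sand0 + runif(3, -0.03, 0.03), 0.5), 0.95)
      clay <- pmin(pmax(clay0 + runif(3, -0.01, 0.01), 0.01), 0.12)
      tibble::tibble(
        site_id = site_id[i], top_cm = lay$top_cm, bottom_cm = lay$bottom_cm,
        sand = sand, silt = 1 - sand - clay, clay = clay,
        bulk_density = runif(3, 1.3, 1.6),
        stone_fraction = runif(3, 0, 0.15))
    })
    soil_table <- do.call(rbind, soil_rows)

    structure(list(site_table = site_table, tree_table = tree_table,
                   stand_table = stand_table, branch_table = branch_table,
                   soil_table = soil_table, climate_table = climate_table,
                   true_traits = NULL, cavitron = NULL, config = config),
              class = "synthetic_study")
  })
}

# z-scores within the simulated dataset; a zero-variance covariate
# (e.g. single-tree designs) contributes 0 rather than NaN.
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate true branch-level traits
#'
#' Generates the latent (noise-free) trait values for every measured
#' branch from the linear mixed-model structure
#' \deqn{y = \beta_0 + \sum_k \beta_k z(x_k) + b_{site} + \varepsilon,}
#' with \eqn{b_{site} \sim N(0, \sigma^2_{site})} and
#' \eqn{\varepsilon \sim N(0, \sigma^2_{resid})}, independently for P50,
#' log slope and Ks. Predictors (CWB, AWC, height, log branch age, Hegyi
#' CI) are standardised within the simulated dataset, so effect sizes are
#' on the per-SD scale and intercepts equal population trait means. The
#' slope is `exp(log_slope)`; Kmax of the conductivity model equals the
#' (specific) Ks; P12 and P88 follow from the closed-form quantile
#' inversion. The branch table's flushed maximum conductivity `max_kh` is
#' back-computed from Ks and the xylem-area allometry so that the
#' covariate pipeline recovers Ks exactly.
#'
#' @param study A `synthetic_study` from [simulate_covariates()].
#' @param config The same [study_config()].
#' @return The study with `true_traits` filled: tibble with `branch_id`,
#'   `tree_id`, `site_id`, `p50`, `slope`, `kmax`, `p12`, `p88`, `ks`,
#'   and the covariates used.
#' @export
simulate_true_traits <- function(study, config = study$config) {
  stopifnot(inherits(study, "synthetic_study"))
  for (tb in c("site_table", "tree_table", "stand_table", "branch_table"))
    if (is.null(study[[tb]]))
      stopf("simulate_true_traits(): study lacks %s", tb)

  stand <- study$stand_table
  trees <- study$tree_table
  branches <- study$branch_table
  sites <- study$site_table

  ci <- vapply(trees$tree_id, function(id) {
    st <- stand[stand$site_id == stand$site_id[match(id, stand$tree_id)], ]
    nb <- nearest_neighbours(st, target_ids = id, n = 3L)
    hegyi_index(st$dbh[match(id, st$tree_id)], nb$dbh_neighbour, nb$distance)
  }, numeric(1))

  b <- branches[match(trees$tree_id, branches$tree_id), ]
  age <- mean_branch_age(b$rings_basipetal, b$rings_acropetal)
  si <- match(trees$site_id, sites$site_id)

  cov <- tibble::tibble(
    branch_id = b$branch_id, tree_id = trees$tree_id,
    site_id = trees$site_id,
    cwb = sites$cwb[si], awc = sites$awc[si], height = trees$height,
    branch_age = age, ci = unname(ci))
  z <- list(cwb = zscore(cov$cwb), awc = zscore(cov$awc),
            height = zscore(cov$height), log_age = zscore(log(cov$branch_age)),
            ci = zscore(cov$ci))

  n <- nrow(cov)
  with_seed(child_seed(config$seed, "traits"), {
    site_ids <- sites$site_id
    vals <- list()
    for (t in c("p50", "log_slope", "ks")) {
      bsite <- rnorm(length(site_ids), 0, config$site_sd[[t]])
      eps <- rnorm(n, 0, config$residual_sd[[t]])
      beta <- config$fixed_effects[[t]]
      lin <- config$intercepts[[t]] +
        Reduce(`+`, lapply(names(beta), function(p) beta[[p]] * z[[p]]))
      vals[[t]] <- lin + bsite[match(cov$site_id, site_ids)] + eps
    }
    # Ks is a positive trait; redraw the residual for the rare draw at or
    # below a small floor instead of clipping
    low <- vals$ks < 0.05
    while (any(low)) {
      beta <- config$fixed_effects$ks
      lin <- config$intercepts[["ks"]] +
        Reduce(`+`, lapply(names(beta), function(p)
          beta[[p]] * z[[p]][low]))
      vals$ks[low] <- lin + rnorm(sum(low), 0, config$residual_sd[["ks"]])
      low <- vals$ks < 0.05
    }

    slope <- exp(vals$log_slope)
    traits <- cbind(cov, tibble::tibble(
      p50 = vals$p50, slope = slope, kmax = vals$ks, ks = vals$ks,
      p12 = pressure_at_loss(vals$p50, slope, 0.12),
      p88 = pressure_at_loss(vals$p50, slope, 0.88)))

    a_xyl <- xylem_area(pi * (b$basipetal_diameter_mm / 2)^2)
    study$branch_table$max_kh[match(b$branch_id,
                                    study$branch_table$branch_id)] <-
      traits$ks * a_xyl * MM2_TO_M2

    study$true_traits <- tibble::as_tibble(traits)
    study
  })
}

#' Simulate one cavitron measurement series
#'
#' Builds the pressure schedule of a flow-centrifuge run: starting at
#' `start_pressure` and descending in steps of `pressure_step`, the run
#' stops at the first pressure where the modelled loss of conductivity
#' reaches 90\% (the instrument's stopping rule); the grid is extended to a
#' minimum of 5 observations if the curve is exhausted sooner. Observed
#' conductivities are the model values plus additive Gaussian noise with
#' SD `noise_cv * kmax`, truncated at zero.
#'
#' @param kmax,p50,slope True curve parameters (`kmax > 0`, `p50 < 0`,
#'   `slope > 0`).
#' @param config A [study_config()] supplying `noise_cv`, `pressure_step`,
#'   `start_pressure`.
#' @param branch_id Identifier attached to the series.
#' @param seed RNG seed for the measurement noise.
#' @return A [cavitron_series()].
#' @export
simulate_cavitron_series <- function(kmax, p50, slope,
                                     config = study_config(),
                                     branch_id = "sim",
                                     seed = config$seed) {
  assert_number(kmax, "kmax", 0, strict_lower = TRUE)
  assert_number(slope, "slope", 0, strict_lower = TRUE)
  if (p50 >= 0) stopf("simulate_cavitron_series(): p50 must be < 0")
  step <- config$pressure_step
  if (step >= 0) stopf("simulate_cavitron_series(): pressure_step must be < 0")

  # first grid pressure with >= 90% modelled loss
  p_stop <- pressure_at_loss(p50, slope, 0.90)
  n_steps <- max(ceiling((p_stop - config$start_pressure) / step), 4)
  pressure <- config$start_pressure + step * (0:n_steps)
  expected <- vc_conductivity(pressure, kmax, p50, slope)

  obs <- with_seed(seed, {
    pmax(expected + rnorm(length(expected), 0, config$noise_cv * kmax), 0)
  })
  cavitron_series(branch_id, pressure, obs)
}

#' Simulate a complete synthetic study
#'
#' Chains [simulate_covariates()], [simulate_true_traits()] and
#' [simulate_cavitron_series()] (one series per branch, each with its own
#' child seed) into a full synthetic dataset with the statistical
#' structure the downstream analysis assumes. Identical configs give
#' byte-identical studies.
#'
#' @param config A [study_config()].
#' @return A `synthetic_study` with all tables, `true_traits`, and a
#'   `cavitron` list of [cavitron_series()] keyed by branch id.
#' @export
simulate_study <- function(config = study_config()) {
  study <- simulate_covariates(config)
  study <- simulate_true_traits(study, config)
  tt <- study$true_traits
  cav_seed <- child_seed(config$seed, "cavitron")
  study$cavitron <- with_seed(cav_seed, {
    seeds <- sample.int(2^31 - 2, nrow(tt))
    out <- lapply(seq_len(nrow(tt)), function(i)
      simulate_cavitron_series(tt$kmax[i], tt$p50[i], tt$slope[i],
                               config, branch_id = tt$branch_id[i],
                               seed = seeds[i]))
    names(out) <- tt$branch_id
    out
  })
  study
}

#' @method print synthetic_study
#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic hydraulic-trait study: %d sites x %d trees (seed %d)\n",
              x$config$n_sites, x$config$n_trees_per_site, x$config$seed))
  cat(sprintf("  tables: %d sites, %d sampled trees (%d mapped), %d branches\n",
              nrow(x$site_table), nrow(x$tree_table), nrow(x$stand_table),
              nrow(x$branch_table)))
  if (!is.null(x$cavitron))
    cat(sprintf("  cavitron series: %d (%.0f obs median)\n",
                length(x$cavitron),
                median(vapply(x$cavitron, nrow, numeric(1)))))
  invisible(x)
}
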