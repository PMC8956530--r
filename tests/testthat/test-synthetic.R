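test_that("study configuration validates its invariants", {
  expect_s3_class(study_config(), "study_config")
  expect_error(study_config(n_sites = 0), "n_sites")
  expect_error(study_config(pressure_step = 0.25), "negative")
  expect_error(study_config(noise_cv = -0.1), "noise_cv")
  expect_error(
    study_config(covariate_ranges = list(awc = c(301, 43.4))), "min > max")
})

test_that("identical seeds give identical studies; different seeds differ", {
  cfg <- study_config(n_sites = 3, seed = 123)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$site_table, s2$site_table)
  expect_identical(s1$tree_table, s2$tree_table)
  expect_identical(s1$branch_table, s2$branch_table)
  expect_identical(s1$true_traits, s2$true_traits)
  expect_identical(s1$cavitron, s2$cavitron)
  s3 <- simulate_study(study_config(n_sites = 3, seed = 124))
  expect_false(identical(s1$site_table, s3$site_table))
})

test_that("simulated covariates respect the configured ranges and design", {
  cfg <- study_config(n_sites = 10, seed = 5)
  st <- simulate_covariates(cfg)
  cr <- cfg$covariate_ranges
  expect_true(all(st$site_table$awc >= cr$awc[1] & st$site_table$awc <= cr$awc[2]))
  expect_true(all(st$site_table$cwb >= cr$cwb[1] & st$site_table$cwb <= cr$cwb[2]))
  expect_true(all(st$site_table$map >= cr$map[1] & st$site_table$map <= cr$map[2]))
  expect_true(all(st$tree_table$dbh >= cr$dbh[1] & st$tree_table$dbh <= cr$dbh[2]))
  expect_true(all(st$tree_table$height >= cr$height[1] &
                    st$tree_table$height <= cr$height[2]))
  expect_equal(nrow(st$site_table), 10)
  expect_equal(nrow(st$tree_table), 100)
  expect_equal(nrow(st$branch_table), 100)
  # every branch maps to one tree, every tree to one site
  expect_true(all(st$branch_table$tree_id %in% st$tree_table$tree_id))
  expect_true(all(st$tree_table$site_id %in% st$site_table$site_id))
  age <- mean_branch_age(st$branch_table$rings_basipetal,
                         st$branch_table$rings_acropetal)
  expect_true(all(age >= 1.5 & age <= 20.5))

  # minimal design: single-row site and tree tables
  st1 <- simulate_covariates(study_config(n_sites = 1, n_trees_per_site = 1,
                                          seed = 2))
  expect_equal(nrow(st1$site_table), 1)
  expect_equal(nrow(st1$tree_table), 1)
})

test_that("true traits follow the configured mixed-model structure", {
  # degenerate variances: every true P50 equals the intercept
  cfg0 <- study_config(
    n_sites = 3, seed = 9,
    fixed_effects = list(
      p50 = c(cwb = 0, awc = 0, height = 0, log_age = 0, ci = 0),
      log_slope = c(cwb = 0, awc = 0, height = 0, log_age = 0, ci = 0),
      ks = c(cwb = 0, awc = 0, height = 0, log_age = 0, ci = 0)),
    site_sd = c(p50 = 0, log_slope = 0, ks = 0),
    residual_sd = c(p50 = 1e-9, log_slope = 1e-9, ks = 1e-9))
  tt <- simulate_true_traits(simulate_covariates(cfg0))$true_traits
  expect_equal(tt$p50, rep(-3.381, nrow(tt)), tolerance = 1e-6)
  expect_equal(tt$slope, rep(exp(1.049), nrow(tt)), tolerance = 1e-5)

  # variance of site means ~ site_sd^2 + residual_sd^2 / n_trees at many sites
  cfg <- study_config(n_sites = 400, n_trees_per_site = 10, seed = 303)
  tt <- simulate_true_traits(simulate_covariates(cfg))$true_traits
  # remove the fixed-effect part site-by-site is unnecessary: effects are
  # small; compare against total expected between-site spread
  v_obs <- var(tapply(tt$p50, tt$site_id, mean))
  v_exp <- 0.199^2 + 0.279^2 / 10
  expect_gt(v_obs, v_exp * 0.75)
  expect_lt(v_obs, v_exp * 1.35)
})

test_that("cavitron series follow the instrument schedule and noise model", {
  cfg <- study_config()
  ser <- simulate_cavitron_series(2, -3.0, 2.0, cfg, seed = 4)
  expect_s3_class(ser, "cavitron_series")
  expect_equal(ser$pressure[1], -0.37)
  expect_equal(diff(ser$pressure), rep(-0.25, nrow(ser) - 1))
  # terminates at the first grid pressure past 90% modelled loss:
  # P50 - ln(9)/s = -3 - ln(9)/2 ~ -4.0986
  p_stop <- -3 - log(9) / 2
  expect_lte(min(ser$pressure), p_stop)
  expect_gt(min(ser$pressure) + 0.25, p_stop)
  expect_true(all(ser$conductivity >= 0))
  expect_gte(nrow(ser), 5)

  # zero noise reproduces the model curve exactly
  cfg0 <- study_config(noise_cv = 0)
  ser0 <- simulate_cavitron_series(2, -3.0, 2.0, cfg0, seed = 4)
  expect_equal(ser0$conductivity,
               vc_conductivity(ser0$pressure, 2, -3.0, 2.0), tolerance = 1e-12)

  expect_error(simulate_cavitron_series(-1, -3, 2, cfg), "kmax")
  expect_error(
    simulate_cavitron_series(2, -3, 2, study_config(pressure_step = 0.25)),
    "negative")
})

test_that("site Hegyi means land in the observed competition range", {
  cfg <- study_config(n_sites = 12, seed = 88)
  study <- simulate_true_traits(simulate_covariates(cfg))
  site_ci <- tapply(study$true_traits$ci, study$true_traits$site_id, mean)
  expect_true(all(site_ci > 0.2 & site_ci < 1.0))
  expect_gt(diff(range(site_ci)), 0.1)
})
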