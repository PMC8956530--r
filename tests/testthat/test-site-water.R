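test_that("monthly climatic water balance is precipitation minus PET", {
  expect_equal(monthly_cwb(50, 50), 0)
  expect_equal(monthly_cwb(50, 60), -10)
  expect_equal(monthly_cwb(c(100, 0), c(20, 5)), c(80, -5))
  expect_error(monthly_cwb(-1, 5), ">= 0")
})

test_that("climate aggregation reproduces constant and generated inputs", {
  years <- 2001:2003
  grid <- expand.grid(month = 1:12, year = years)
  m <- tibble::tibble(site_id = "A", year = grid$year, month = grid$month,
                      precip_mm = 50, pet_mm = 40, temp_C = 9.5)
  agg <- aggregate_climate(m, years)
  expect_equal(agg$map, 600)
  expect_equal(agg$mat, 9.5)
  expect_equal(agg$msp, 150)
  expect_equal(agg$cwb, 10)

  # generator round trip: aggregates equal the configured site values
  cfg <- study_config(n_sites = 4, seed = 31)
  st <- simulate_covariates(cfg)
  agg <- aggregate_climate(st$climate_table, cfg$years)
  agg <- agg[match(st$site_table$site_id, agg$site_id), ]
  expect_equal(agg$map, st$site_table$map, tolerance = 1e-12)
  expect_equal(agg$mat, st$site_table$mat, tolerance = 1e-12)
  expect_equal(agg$cwb, st$site_table$cwb, tolerance = 1e-12)

  expect_error(aggregate_climate(m[-5, ], years), "missing months")
})

test_that("pF conversion matches the conventional reference points", {
  # -1.5 MPa is pF 4.2 and -60 hPa (-0.006 MPa) is pF 1.8 to one decimal
  expect_equal(round(pF_of_potential(-1.5), 1), 4.2)
  expect_equal(round(pF_of_potential(-60 * 1e-4), 1), 1.8)
  expect_equal(pF_of_potential(-1e-4), 0)  # -1 hPa
  expect_error(pF_of_potential(0.1), "< 0")
  # inverse round-trips to high precision
  set.seed(4)
  pf <- runif(50, 0, 6)
  expect_equal(pF_of_potential(potential_of_pF(pf)), pf, tolerance = 1e-12)
})

test_that("van Genuchten retention curve has the closed-form value and limits", {
  p <- vg_params(0.05, 0.40, 0.02, 1.5)
  expect_equal(vg_theta(p, 0), 0.40)
  expect_equal(vg_theta(p, 1e12), 0.05, tolerance = 1e-4)
  # hand evaluation at h = 60 cm: theta_r + (theta_s-theta_r)(1+(1.2)^1.5)^(-1/3)
  expect_equal(vg_theta(p, 60),
               0.05 + 0.35 * (1 + 1.2^1.5)^(-(1 - 1 / 1.5)),
               tolerance = 1e-12)
  expect_equal(round(vg_theta(p, 60), 4), 0.3146)
  expect_error(vg_params(0.4, 0.2, 0.02, 1.5), "theta_r < theta_s")
  expect_error(vg_params(0.05, 0.4, 0.02, 0.9), "n")
})

test_that("retention is monotone non-increasing in suction for random parameters", {
  set.seed(8)
  for (i in 1:30) {
    p <- vg_params(runif(1, 0, 0.15), runif(1, 0.3, 0.55),
                   runif(1, 0.001, 0.1), runif(1, 1.05, 3.5))
    h <- sort(runif(40, 0, 1e5))
    th <- vg_theta(p, h)
    expect_true(all(diff(th) <= 1e-15))
    expect_true(all(th >= p$theta_r - 1e-12 & th <= p$theta_s + 1e-12))
  }
})

test_that("texture triangle classification and lookup behave per the class rules", {
  expect_equal(texture_class(1, 0, 0), "sand")
  expect_equal(texture_class(0.4, 0.4, 0.2), "loam")
  expect_equal(texture_class(0.1, 0.85, 0.05), "silt")
  expect_equal(texture_class(0.2, 0.2, 0.6), "clay")
  expect_equal(texture_class(0.05, 0.5, 0.45), "silty clay")
  expect_error(texture_class(0.5, 0.3, 0.1), "sum to 1")

  vg_sand <- texture_to_vg(1, 0, 0)
  tab <- vg_class_table()
  expect_equal(vg_sand$theta_s, tab$theta_s[tab$class == "sand"])
  expect_equal(vg_sand$n, tab$n[tab$class == "sand"])
  # override path passes external parameters through unchanged
  ov <- vg_params(0.03, 0.42, 0.015, 1.8)
  expect_identical(texture_to_vg(0.4, 0.4, 0.2, override = ov), ov)
})

test_that("profile AWC integrates field-capacity minus wilting-point water", {
  # uniform delta-theta of 0.15 over 100 cm is exactly 150 mm:
  # build parameters with theta(FC)-theta(PWP) = 0.15 via a near-step curve
  flat <- vg_params(0.10, 0.25, 1e-6, 1.2)  # stays ~theta_s at FC, -> use wide
  prof1 <- data.frame(top_cm = 0, bottom_cm = 100)
  d_theta <- vg_theta(flat, (10^1.8) / 0.980665) -
    vg_theta(flat, (10^4.2) / 0.980665)
  expect_equal(profile_awc(prof1, list(flat)), d_theta * 100 * 10,
               tolerance = 1e-12)

  # degenerate retention: theta_r ~ theta_s gives AWC ~ 0
  deg <- vg_params(0.2499999, 0.25, 0.02, 1.5)
  expect_lt(profile_awc(prof1, list(deg)), 1e-3)

  # additivity: splitting a layer changes nothing
  p <- vg_params(0.05, 0.40, 0.02, 1.5)
  whole <- profile_awc(data.frame(top_cm = 0, bottom_cm = 100), list(p))
  split <- profile_awc(data.frame(top_cm = c(0, 10, 30), bottom_cm = c(10, 30, 100)),
                       list(p, p, p))
  expect_equal(whole, split, tolerance = 1e-12)

  # extrapolation: the 30-60 layer parameters fill 60-100
  p2 <- vg_params(0.04, 0.38, 0.03, 1.7)
  three <- profile_awc(data.frame(top_cm = c(0, 10, 30), bottom_cm = c(10, 30, 60)),
                       list(p, p, p2))
  four <- profile_awc(data.frame(top_cm = c(0, 10, 30, 60),
                                 bottom_cm = c(10, 30, 60, 100)),
                      list(p, p, p2, p2))
  expect_equal(three, four, tolerance = 1e-12)

  # AWC is never negative; optional stone correction shrinks it
  expect_gte(whole, 0)
  stony <- data.frame(top_cm = 0, bottom_cm = 100, stone_fraction = 0.2)
  expect_equal(profile_awc(stony, list(p), correct_stones = TRUE),
               0.8 * whole, tolerance = 1e-12)

  expect_error(profile_awc(data.frame(top_cm = c(0, 20), bottom_cm = c(10, 60)),
                           list(p, p)), "contiguous")
})

test_that("synthetic sandy profiles give AWC within the observed site range", {
  cfg <- study_config(n_sites = 12, seed = 61)
  st <- simulate_covariates(cfg)
  for (sid in st$site_table$site_id) {
    prof <- st$soil_table[st$soil_table$site_id == sid, ]
    params <- lapply(seq_len(nrow(prof)), function(i)
      texture_to_vg(prof$sand[i], prof$silt[i], prof$clay[i]))
    awc <- profile_awc(prof, params)
    expect_gte(awc, 43.4)
    expect_lte(awc, 301.0)
  }
})
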