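test_that("model frame preparation standardises and transforms correctly", {
  tab <- make_trait_table()
  prep <- prepare_model_frame(tab)
  for (col in c("cwb_z", "awc_z", "height_z", "log_age_z", "ci_z")) {
    expect_equal(mean(prep$frame[[col]]), 0, tolerance = 1e-12)
    expect_equal(sd(prep$frame[[col]]), 1, tolerance = 1e-12)
  }
  # branch age enters as its natural log before scaling
  i <- match("log_age", prep$scaling$predictor)
  expect_equal(prep$frame$log_age_z * prep$scaling$scale[i] +
                 prep$scaling$centre[i], log(tab$branch_age),
               tolerance = 1e-12)
  expect_equal(prep$frame$log_slope, log(tab$slope), tolerance = 1e-12)

  tab2 <- tab
  tab2$height <- 25
  expect_error(prepare_model_frame(tab2), "zero-variance")
  expect_error(prepare_model_frame(tab[, -2]), "missing columns")
})

test_that("per-SD coefficients back-transform to the raw predictor scale", {
  tab <- make_trait_table(seed = 12)
  prep <- prepare_model_frame(tab)
  m <- fit_lmm(prep$frame, "p50")
  est_z <- m$coefficients$estimate[m$coefficients$term == "awc_z"]
  est_raw <- unname(unscale_coefficient(est_z, "awc", prep$scaling))
  # oracle: refit on the unscaled predictor; slope must match
  frame2 <- prep$frame
  frame2$awc_raw <- tab$awc
  f2 <- lmerTest::lmer(p50 ~ cwb_z + awc_raw + height_z + log_age_z + ci_z +
                         (1 | site_id), data = frame2, REML = TRUE)
  expect_equal(est_raw, lme4::fixef(f2)[["awc_raw"]], tolerance = 1e-8)
})

test_that("with no site variance the mixed model reduces to least squares", {
  tab <- make_trait_table(site_sd = 0, seed = 42)
  prep <- prepare_model_frame(tab)
  m <- fit_lmm(prep$frame, "p50")
  ols <- lm(p50 ~ cwb_z + awc_z + height_z + log_age_z + ci_z,
            data = prep$frame)
  expect_true(m$singular || m$site_sd < 0.05)
  if (m$singular) {
    expect_equal(m$coefficients$estimate, unname(coef(ols)), tolerance = 1e-6)
    expect_equal(m$marginal_r2, m$conditional_r2, tolerance = 1e-12)
  }
})

test_that("duplicating every row barely moves the point estimates", {
  # exact invariance holds for least squares; under REML the duplicated
  # within-site sample size shifts the GLS weights slightly, so estimates
  # are only near-invariant
  tab <- make_trait_table(seed = 7)
  prep1 <- prepare_model_frame(tab)
  prep2 <- prepare_model_frame(rbind(tab, tab))
  m1 <- fit_lmm(prep1$frame, "p50")
  m2 <- fit_lmm(prep2$frame, "p50")
  expect_lt(max(abs(m1$coefficients$estimate - m2$coefficients$estimate)),
            0.02)
  ols1 <- lm(p50 ~ cwb_z + awc_z + height_z + log_age_z + ci_z,
             data = prep1$frame)
  ols2 <- lm(p50 ~ cwb_z + awc_z + height_z + log_age_z + ci_z,
             data = rbind(prep1$frame, prep1$frame))
  expect_equal(unname(coef(ols1)), unname(coef(ols2)), tolerance = 1e-9)
})

test_that("REML variance components match the balanced closed-form oracle", {
  set.seed(55)
  g <- 5; n <- 8
  group <- rep(sprintf("g%d", 1:g), each = n)
  y <- rnorm(g, 0, 0.6)[rep(1:g, each = n)] + rnorm(g * n, 0, 0.4)
  oracle <- reml_balanced_oneway(y, group)

  fit <- lme4::lmer(y ~ 1 + (1 | group), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(vc$vcov[vc$grp == "group"], oracle$sigma_b2, tolerance = 1e-6)
  expect_equal(vc$vcov[vc$grp == "Residual"], oracle$sigma_e2, tolerance = 1e-6)
  expect_equal(lme4::fixef(fit)[["(Intercept)"]], oracle$intercept,
               tolerance = 1e-9)

  # and the generic closed-form REML log-likelihood peaks at the same spot
  X <- matrix(1, length(y), 1)
  ll_oracle <- reml_loglik(log(c(oracle$sigma_b2, oracle$sigma_e2)), y, X, group)
  ll_lmer <- reml_loglik(log(vc$vcov[c(match("group", vc$grp),
                                       match("Residual", vc$grp))]),
                         y, X, group)
  expect_equal(ll_lmer, ll_oracle, tolerance = 1e-6)
  opt <- optim(c(0, 0), function(th) -reml_loglik(th, y, X, group),
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(exp(opt$par[1]), oracle$sigma_b2, tolerance = 1e-4)
  expect_equal(exp(opt$par[2]), oracle$sigma_e2, tolerance = 1e-4)
})

test_that("Satterthwaite df matches the balanced one-way closed form", {
  set.seed(66)
  g <- 6; n <- 10
  frame <- tibble::tibble(site_id = factor(rep(sprintf("g%d", 1:g), each = n)))
  y <- rnorm(g, 0, 0.8)[rep(1:g, each = n)] + rnorm(g * n, 0, 0.5)
  fit <- lmerTest::lmer(y ~ 1 + (1 | site_id), data = frame, REML = TRUE)
  smr <- summary(fit, ddf = "Satterthwaite")$coefficients
  # the intercept variance is MSB/(gn); its df is that of MSB: g - 1
  expect_equal(unname(smr[1, "df"]), g - 1, tolerance = 1e-3)
})

test_that("Wald t tests report estimate/SE ratios with two-sided p-values", {
  tab <- make_trait_table(seed = 21)
  m <- fit_lmm(prepare_model_frame(tab)$frame, "p50")
  w <- wald_t_tests(m)
  expect_equal(w$t, w$estimate / w$se, tolerance = 1e-12)
  expect_equal(w$p, 2 * stats::pt(-abs(w$t), w$df), tolerance = 1e-12)
})

test_that("R2 decomposition identities hold on every fit", {
  for (seed in c(1, 2, 3)) {
    tab <- make_trait_table(seed = seed)
    m <- fit_lmm(prepare_model_frame(tab)$frame, "p50")
    r2 <- nakagawa_r2(m)
    vf <- variance_fractions(m)
    expect_gte(r2[["marginal"]], 0)
    expect_lte(r2[["marginal"]], r2[["conditional"]])
    expect_lte(r2[["conditional"]], 1)
    expect_equal(sum(vf), 1, tolerance = 1e-9)
    expect_equal(vf[["fixed"]], r2[["marginal"]], tolerance = 1e-12)
    expect_equal(vf[["site"]], r2[["conditional"]] - r2[["marginal"]],
                 tolerance = 1e-12)
  }
})

test_that("omitting a genuine site effect inflates the residual variance", {
  tab <- make_trait_table(n_sites = 12, site_sd = 0.5, seed = 31)
  prep <- prepare_model_frame(tab)
  m <- fit_lmm(prep$frame, "p50")
  ols <- lm(p50 ~ cwb_z + awc_z + height_z + log_age_z + ci_z,
            data = prep$frame)
  expect_gt(summary(ols)$sigma, m$residual_sd)
})

test_that("correlation screen flags collinear pairs and only those", {
  set.seed(19)
  tab <- tibble::tibble(a = rnorm(300), b = rnorm(300), c = rnorm(300))
  tab$d <- 2 * tab$a + 3  # affine copy: r = 1 exactly
  sc <- correlation_screen(tab)
  expect_equal(diag(sc$correlations), rep(1, 4), ignore_attr = TRUE)
  expect_equal(sc$correlations["a", "d"], 1, tolerance = 1e-12)
  expect_true(nrow(sc$flagged) == 1 &&
                all(sort(c(sc$flagged$var1, sc$flagged$var2)) == c("a", "d")))
  # independent predictors at n = 300 stay below the threshold
  sc2 <- correlation_screen(tab[, c("a", "b", "c")])
  expect_equal(nrow(sc2$flagged), 0)
  tab$e <- 1
  expect_error(correlation_screen(tab), "constant")
})
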