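# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Root-finding inversion of the logistic loss function: the pressure at
# which loss_fraction equals q, found by bisection on a wide bracket.
pressure_at_loss_numeric <- function(p50, slope, q, tol = 1e-12) {
  f <- function(psi) 1 / (1 + exp(slope * (psi - p50))) - q
  stats::uniroot(f, lower = p50 - 60 / slope, upper = p50 + 60 / slope,
                 tol = tol)$root
}

# Brute-force nearest-neighbour selection: full distance matrix, ties by
# tree_id order.
nearest_neighbours_brute <- function(trees, id, n = 3L) {
  i <- match(id, trees$tree_id)
  d <- sqrt((trees$x - trees$x[i])^2 + (trees$y - trees$y[i])^2)
  ord <- order(d, trees$tree_id)
  ord <- ord[trees$tree_id[ord] != id][seq_len(n)]
  list(dbh = trees$dbh[ord], dist = d[ord])
}

# Closed-form REML estimates for the balanced one-way random-intercept
# model: with g groups of size n, MSW estimates sigma_e^2 and
# (MSB - MSW)/n estimates sigma_b^2 (method-of-moments equals REML in the
# balanced interior case). Fixed intercept is the grand mean.
reml_balanced_oneway <- function(y, group) {
  g <- length(unique(group))
  n <- length(y) / g
  gm <- mean(y)
  means <- tapply(y, group, mean)
  msb <- n * sum((means - gm)^2) / (g - 1)
  msw <- sum((y - means[group])^2) / (g * (n - 1))
  list(intercept = gm, sigma_b2 = max((msb - msw) / n, 0), sigma_e2 = msw,
       msb = msb, msw = msw)
}

# Direct maximization of the closed-form REML log-likelihood of the
# random-intercept model (profile over beta), generic design.
reml_loglik <- function(theta, y, X, group) {
  s2b <- exp(theta[1L]); s2e <- exp(theta[2L])
  Z <- stats::model.matrix(~ 0 + factor(group))
  V <- s2b * tcrossprod(Z) + s2e * diag(length(y))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            t(r) %*% Vi %*% r)[1L]
}

# A small hand-built trait table with the full predictor schema.
make_trait_table <- function(n_sites = 6, n_trees = 8, seed = 99,
                             site_sd = 0.2, resid_sd = 0.3,
                             beta = c(cwb = 0, awc = 0.1, height = 0,
                                      log_age = 0.1, ci = 0)) {
  set.seed(seed)
  site <- rep(sprintf("s%02d", 1:n_sites), each = n_trees)
  n <- length(site)
  tab <- tibble::tibble(
    site_id = site,
    cwb = rep(runif(n_sites, -10, 25), each = n_trees),
    awc = rep(runif(n_sites, 50, 300), each = n_trees),
    height = runif(n, 21, 34),
    branch_age = exp(runif(n, log(1.5), log(20))),
    ci = runif(n, 0.3, 0.8))
  z <- function(x) (x - mean(x)) / sd(x)
  lin <- -3.381 + beta[["cwb"]] * z(tab$cwb) + beta[["awc"]] * z(tab$awc) +
    beta[["height"]] * z(tab$height) + beta[["log_age"]] * z(log(tab$branch_age)) +
    beta[["ci"]] * z(tab$ci)
  bsite <- rnorm(n_sites, 0, site_sd)
  tab$p50 <- lin + bsite[match(tab$site_id, unique(tab$site_id))] +
    rnorm(n, 0, resid_sd)
  tab$slope <- exp(rnorm(n, 1.049, 0.28))
  tab$ks <- pmax(rnorm(n, 1.536, 0.5), 0.1)
  tab$p12 <- tab$p50 + log(0.88 / 0.12) / tab$slope
  tab$p88 <- tab$p50 + log(0.12 / 0.88) / tab$slope
  tab
}
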