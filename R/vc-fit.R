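#' Construct and validate a cavitron series
#'
#' A cavitron (flow-centrifuge) series holds the ordered observations for one
#' branch segment: the rotor-imposed xylem pressure (MPa, negative,
#' non-increasing as the run proceeds) and the measured specific
#' conductivity (kg m\eqn{^{-1}} MPa\eqn{^{-1}} s\eqn{^{-1}}, non-negative).
#'
#' @param branch_id Identifier of the branch segment.
#' @param pressure Numeric vector of pressures, MPa; all < 0, sorted from
#'   least to most negative.
#' @param conductivity Numeric vector of conductivities, same length; >= 0.
#' @return A `cavitron_series` object (tibble subclass with a `branch_id`
#'   attribute).
#' @export
cavitron_series <- function(branch_id, pressure, conductivity) {
  if (length(pressure) != length(conductivity))
    stopf("cavitron_series(): pressure and conductivity lengths differ")
  if (length(pressure) < 5L)
    stopf("cavitron_series(): need >= 5 observations, got %d",
          length(pressure))
  if (!all(is.finite(pressure)) || !all(is.finite(conductivity)))
    stopf("cavitron_series(): non-finite values")
  if (any(pressure >= 0))
    stopf("cavitron_series(): pressures must be negative (MPa)")
  if (is.unsorted(rev(pressure), strictly = FALSE))
    stopf("cavitron_series(): pressures must be non-increasing")
  if (any(conductivity < 0))
    stopf("cavitron_series(): conductivities must be >= 0")
  out <- tibble::tibble(pressure = as.numeric(pressure),
                        conductivity = as.numeric(conductivity))
  attr(out, "branch_id") <- as.character(branch_id)
  class(out) <- c("cavitron_series", class(out))
  out
}

# Deterministic self-starting values: Kmax from the plateau, P50 by linear
# interpolation of the half-maximum crossing, s from a logit-linear fit of
# interior loss fractions.
vc_start_values <- function(pressure, conductivity) {
  kmax0 <- max(conductivity)
  half <- kmax0 / 2
  below <- which(conductivity < half)
  if (length(below) == 0L) {
    p50_0 <- min(pressure) - 0.5
  } else {
    i <- min(below)
    if (i == 1L) {
      p50_0 <- pressure[1L]
    } else {
      # interpolate between the bracketing observations
      k1 <- conductivity[i - 1L]; k2 <- conductivity[i]
      w <- (k1 - half) / max(k1 - k2, .Machine$double.eps)
      p50_0 <- pressure[i - 1L] + w * (pressure[i] - pressure[i - 1L])
    }
  }
  frac <- pmin(pmax(conductivity / kmax0, 1e-3), 1 - 1e-3)
  interior <- frac > 0.05 & frac < 0.95
  s0 <- 2
  if (sum(interior) >= 2L) {
    # K/Kmax = 1 - L, so logit(1 - K/Kmax) = s * (psi - P50)
    z <- log((1 - frac[interior]) / frac[interior])
    sl <- stats::coef(stats::lm(z ~ pressure[interior]))[2L]
    if (is.finite(sl) && sl > 0.05) s0 <- as.numeric(sl)
  }
  list(kmax = kmax0, p50 = p50_0, slope = max(s0, 0.1))
}

vc_nls_once <- function(df, start, maxiter = 100) {
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    conductivity ~ kmax * (1 - 1 / (1 + exp(slope * (pressure - p50)))),
    data = df,
    start = start,
    lower = c(kmax = 1e-8, p50 = -30, slope = 1e-3),
    upper = c(kmax = Inf, p50 = -1e-6, slope = 100),
    control = minpack.lm::nls.lm.control(maxiter = maxiter)
  )), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  fit
}

#' Fit the sigmoidal vulnerability curve to one cavitron series
#'
#' Estimates \eqn{(K_{max}, P_{50}, s)} by nonlinear least squares on the
#' conductivities themselves (no conversion to percent loss), then derives
#' P12 and P88 from the closed-form quantile inversion
#' [pressure_at_loss()]. Starting values are deterministic (plateau maximum,
#' interpolated half-maximum crossing, logit-linearised slope); on failure
#' up to `restarts` seeded, jittered restarts are attempted.
#'
#' A series with no observation below 50\% of the maximum observed
#' conductivity cannot identify P50; the fit is returned with
#' `converged = FALSE` and reason `"non-identifiable"`.
#'
#' @param series A [cavitron_series()] (or data frame with `pressure` and
#'   `conductivity` columns).
#' @param restarts Maximum number of jittered restarts after a failed fit.
#' @param seed Seed for the restart jitter (deterministic fits regardless).
#' @return A `vc_fit` object: list with elements `kmax`, `p50`, `slope`,
#'   `p12`, `p88`, `se` (named vector), `converged`, `reason`, `rss`, `n`,
#'   `branch_id`, and the data used.
#' @export
fit_vulnerability_curve <- function(series, restarts = 5, seed = 1L) {
  if (!is.data.frame(series) ||
      !all(c("pressure", "conductivity") %in% names(series)))
    stopf("fit_vulnerability_curve(): need pressure + conductivity columns")
  df <- data.frame(pressure = as.numeric(series$pressure),
                   conductivity = as.numeric(series$conductivity))
  if (nrow(df) < 5L)
    stopf("fit_vulnerability_curve(): need >= 5 observations, got %d",
          nrow(df))
  branch_id <- attr(series, "branch_id")
  if (is.null(branch_id)) branch_id <- NA_character_

  out <- structure(list(
    branch_id = branch_id, kmax = NA_real_, p50 = NA_real_,
    slope = NA_real_, p12 = NA_real_, p88 = NA_real_,
    se = c(kmax = NA_real_, p50 = NA_real_, slope = NA_real_),
    converged = FALSE, reason = "", rss = NA_real_, n = nrow(df),
    data = df), class = "vc_fit")

  if (!any(df$conductivity < 0.5 * max(df$conductivity))) {
    out$reason <- "non-identifiable"
    return(out)
  }

  start <- vc_start_values(df$pressure, df$conductivity)
  fit <- vc_nls_once(df, start)
  if (is.null(fit) && restarts > 0) {
    fit <- with_seed(seed, {
      f <- NULL
      for (r in seq_len(restarts)) {
        jit <- list(kmax = start$kmax * exp(rnorm(1, 0, 0.1)),
                    p50 = start$p50 + rnorm(1, 0, 0.5),
                    slope = start$slope * exp(rnorm(1, 0, 0.3)))
        f <- vc_nls_once(df, jit)
        if (!is.null(f)) break
      }
      f
    })
  }
  if (is.null(fit)) {
    out$reason <- sprintf("no convergence after %d restarts", restarts)
    return(out)
  }

  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    c(kmax = NA_real_, p50 = NA_real_, slope = NA_real_))
  out$kmax <- unname(cf[["kmax"]])
  out$p50 <- unname(cf[["p50"]])
  out$slope <- unname(cf[["slope"]])
  out$p12 <- pressure_at_loss(out$p50, out$slope, 0.12)
  out$p88 <- pressure_at_loss(out$p50, out$slope, 0.88)
  out$se <- c(kmax = unname(se[["kmax"]]), p50 = unname(se[["p50"]]),
              slope = unname(se[["slope"]]))
  out$converged <- TRUE
  out$reason <- "ok"
  out$rss <- sum(stats::residuals(fit)^2)
  out
}

#' @method print vc_fit
#' @export
print.vc_fit <- function(x, ...) {
  cat("Vulnerability-curve fit", if (!is.na(x$branch_id))
    sprintf("(branch %s)", x$branch_id), "\n")
  if (!x$converged) {
    cat("  not converged:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  Kmax = %.4g  P50 = %.3f MPa  slope = %.3f MPa^-1\n",
              x$kmax, x$p50, x$slope))
  cat(sprintf("  P12 = %.3f  P88 = %.3f MPa  (n = %d, RSS = %.3g)\n",
              x$p12, x$p88, x$n, x$rss))
  invisible(x)
}

#' Case-resampling bootstrap for a vulnerability-curve fit
#'
#' Pairs (case) bootstrap of the (pressure, conductivity) observations:
#' resample rows with replacement, refit, and summarise the `B` replicate
#' parameter vectors with percentile 95\% intervals, plus a pointwise 95\%
#' band of the predicted loss curve over the observed pressure range.
#' Replicates that fail to converge are dropped and counted.
#'
#' A cavitron series has few observations (typically 12-22), where raw
#' percentile intervals are systematically narrow. The intervals therefore
#' use the expanded percentile method: the quantile levels are widened to
#' \eqn{\Phi(-\sqrt{n/(n-1)}\, t_{\alpha/2, n-1})}, the standard
#' small-sample calibration of the percentile bootstrap.
#'
#' @param series A [cavitron_series()].
#' @param fit Optional converged [fit_vulnerability_curve()] result for the
#'   same series (computed if missing); its estimates seed the refits.
#' @param B Number of bootstrap replicates (warning recorded if < 100).
#' @param seed RNG seed; identical seeds give identical intervals.
#' @param band_points Number of pressures at which the curve band is
#'   evaluated.
#' @return A `vc_bootstrap` object: `B`, `B_used`, `ci` (3 x 2 matrix of
#'   percentile intervals for kmax, p50, slope), `band` (tibble with
#'   pressure, lower, upper loss), `dropped`, `warnings`.
#' @export
bootstrap_vc <- function(series, fit = NULL, B = 1000L, seed = 1L,
                         band_points = 60L) {
  if (is.null(fit)) fit <- fit_vulnerability_curve(series)
  if (!inherits(fit, "vc_fit") || !fit$converged)
    stopf("bootstrap_vc(): requires a converged vc_fit")
  warnings <- character()
  if (B < 100) warnings <- c(warnings, sprintf("B = %d < 100 replicates", B))
  df <- fit$data
  n <- nrow(df)
  start <- list(kmax = fit$kmax, p50 = fit$p50, slope = fit$slope)

  reps <- with_seed(seed, {
    m <- matrix(NA_real_, nrow = B, ncol = 3L,
                dimnames = list(NULL, c("kmax", "p50", "slope")))
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      d <- df[idx, , drop = FALSE]
      if (!any(d$conductivity < 0.5 * max(d$conductivity))) next
      f <- vc_nls_once(d, start, maxiter = 50)
      if (!is.null(f)) m[b, ] <- coef(f)[c("kmax", "p50", "slope")]
    }
    m
  })
  ok <- stats::complete.cases(reps)
  dropped <- sum(!ok)
  reps <- reps[ok, , drop = FALSE]
  if (nrow(reps) < 2L)
    stopf("bootstrap_vc(): fewer than 2 converged replicates")

  # expanded percentile levels for nominal 95%
  a_exp <- stats::pnorm(-sqrt(n / (n - 1)) * stats::qt(0.975, n - 1))
  ci <- t(apply(reps, 2L, quantile, probs = c(a_exp, 1 - a_exp),
                names = FALSE))
  colnames(ci) <- c("lower", "upper")

  pgrid <- seq(max(df$pressure), min(df$pressure), length.out = band_points)
  loss_mat <- apply(reps, 1L, function(p)
    loss_fraction(pgrid, p[["p50"]], p[["slope"]]))
  band <- tibble::tibble(
    pressure = pgrid,
    lower = apply(loss_mat, 1L, quantile, probs = 0.025, names = FALSE),
    upper = apply(loss_mat, 1L, quantile, probs = 0.975, names = FALSE))

  structure(list(B = B, B_used = nrow(reps), ci = ci, band = band,
                 dropped = dropped, warnings = warnings,
                 estimates = c(kmax = fit$kmax, p50 = fit$p50,
                               slope = fit$slope)),
            class = "vc_bootstrap")
}

#' @method print vc_bootstrap
#' @export
print.vc_bootstrap <- function(x, ...) {
  cat(sprintf("Pairs bootstrap, %d/%d replicates converged\n",
              x$B_used, x$B))
  for (p in rownames(x$ci))
    cat(sprintf("  %-5s %.4g  [%.4g, %.4g]\n", p, x$estimates[[p]],
                x$ci[p, "lower"], x$ci[p, "upper"]))
  if (length(x$warnings)) cat("  warnings:", x$warnings, sep = "\n   ")
  invisible(x)
}

#' Kruskal-Wallis comparison of two trait groups
#'
#' Rank-based comparison of a hydraulic trait between two treatment groups
#' (e.g. P50 of flushed vs non-flushed branches), returning the
#' tie-corrected H statistic and its chi-square p-value (1 df for two
#' groups).
#'
#' @param values_a,values_b Numeric trait values for the two groups, each of
#'   length >= 2.
#' @return List with `h`, `p_value`, `df`, and the group sizes.
#' @export
compare_groups_kruskal <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stopf("compare_groups_kruskal(): each group needs >= 2 values")
  all_vals <- c(values_a, values_b)
  if (length(unique(all_vals)) == 1L)
    stopf("compare_groups_kruskal(): all values identical; H undefined")
  kt <- stats::kruskal.test(list(values_a, values_b))
  list(h = unname(kt$statistic), p_value = unname(kt$p.value),
       df = unname(kt$parameter),
       n = c(a = length(values_a), b = length(values_b)))
}
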