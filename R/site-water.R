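#' Monthly climatic water balance
#'
#' CWB for a month is precipitation minus potential evapotranspiration, in
#' mm; negative values indicate an atmospheric water deficit. Vectorised.
#'
#' @param precipitation Monthly precipitation sum, mm; >= 0.
#' @param pet Monthly potential evapotranspiration, mm; >= 0.
#' @return CWB in mm (may be negative).
#' @export
monthly_cwb <- function(precipitation, pet) {
  if (!all(is.finite(precipitation)) || !all(is.finite(pet)))
    stopf("monthly_cwb(): inputs must be finite")
  if (any(precipitation < 0) || any(pet < 0))
    stopf("monthly_cwb(): precipitation and PET must be >= 0")
  precipitation - pet
}

#' Aggregate a monthly climate table to site summaries
#'
#' For each site over a reference period, computes mean annual precipitation
#' (MAP, mm yr^-1), mean annual temperature (MAT, degC), mean early
#' growing-season precipitation (MSP, Apr-Jun sum), mean growing-season
#' precipitation (MGSP, configurable months), and the mean monthly climatic
#' water balance (CWB, mm month^-1).
#'
#' @param monthly Data frame with columns `site_id`, `year`, `month`,
#'   `precip_mm`, `pet_mm`, `temp_C`.
#' @param years Integer vector of years to include, e.g. `1991:2018`.
#' @param gs_months Months defining the growing season for MGSP
#'   (default April-September).
#' @return Tibble with one row per site: `site_id`, `map`, `mat`, `msp`,
#'   `mgsp`, `cwb`.
#' @export
aggregate_climate <- function(monthly, years, gs_months = 4:9) {
  need <- c("site_id", "year", "month", "precip_mm", "pet_mm", "temp_C")
  miss <- setdiff(need, names(monthly))
  if (length(miss))
    stopf("aggregate_climate(): missing columns: %s",
          paste(miss, collapse = ", "))
  m <- monthly[monthly$year %in% years, , drop = FALSE]
  if (any(!m$month %in% 1:12)) stopf("aggregate_climate(): months must be 1-12")

  # every site must have all 12 months of every requested year
  gaps <- do.call(rbind, lapply(split(m, m$site_id), function(d) {
    full <- expand.grid(year = years, month = 1:12)
    have <- paste(d$year, d$month)
    missing <- full[!paste(full$year, full$month) %in% have, , drop = FALSE]
    if (nrow(missing))
      data.frame(site_id = d$site_id[1L], missing)
  }))
  if (!is.null(gaps) && nrow(gaps))
    stopf("aggregate_climate(): missing months, e.g. site %s year %d month %d (%d total)",
          gaps$site_id[1L], gaps$year[1L], gaps$month[1L], nrow(gaps))

  res <- lapply(split(m, m$site_id), function(d) {
    ann_p <- tapply(d$precip_mm, d$year, sum)
    ann_t <- tapply(d$temp_C, d$year, mean)
    msp_y <- tapply(d$precip_mm[d$month %in% 4:6], d$year[d$month %in% 4:6], sum)
    gs <- d$month %in% gs_months
    mgsp_y <- tapply(d$precip_mm[gs], d$year[gs], sum)
    tibble::tibble(site_id = d$site_id[1L],
                   map = mean(ann_p), mat = mean(ann_t),
                   msp = mean(msp_y), mgsp = mean(mgsp_y),
                   cwb = mean(monthly_cwb(d$precip_mm, d$pet_mm)))
  })
  out <- do.call(rbind, res)
  out[order(out$site_id), , drop = FALSE]
}

# 1 hPa of matric suction = 1/(rho g) m of water column = 1.019716 cm.
# Derived from rho = 1000 kg m^-3, g = 9.80665 m s^-2.
CM_PER_HPA <- 1 / 0.980665

#' pF from water potential
#'
#' pF is the decimal logarithm of matric suction expressed in hPa;
#' a potential of -1 MPa corresponds to 10^4 hPa. The conventional points
#' are field capacity at -60 hPa (pF 1.8) and permanent wilting point at
#' -1.5 MPa (pF 4.2).
#'
#' @param potential_mpa Water potential in MPa, strictly negative.
#' @return pF (dimensionless).
#' @seealso [potential_of_pF()] for the inverse.
#' @export
pF_of_potential <- function(potential_mpa) {
  if (!all(is.finite(potential_mpa)) || any(potential_mpa >= 0))
    stopf("pF_of_potential(): potential must be finite and < 0")
  log10(-potential_mpa * 1e4)
}

#' @param pf pF value.
#' @rdname pF_of_potential
#' @return `potential_of_pF()`: water potential in MPa (negative).
#' @export
potential_of_pF <- function(pf) {
  if (!all(is.finite(pf))) stopf("potential_of_pF(): pf must be finite")
  -(10^pf) / 1e4
}

#' van Genuchten retention parameters
#'
#' Parameter set of the closed-form van Genuchten retention curve
#' \eqn{\theta(h) = \theta_r + (\theta_s - \theta_r)\,[1 + (\alpha h)^n]^{-m}}
#' with \eqn{m = 1 - 1/n} and suction \eqn{h} in cm of water.
#'
#' @param theta_r Residual volumetric water content, in \[0, theta_s).
#' @param theta_s Saturated volumetric water content, in (theta_r, 1\].
#' @param alpha Inverse air-entry suction, cm^-1, > 0.
#' @param n Shape parameter, > 1.
#' @return A `vg_params` list with `theta_r`, `theta_s`, `alpha`, `n`, `m`.
#' @export
vg_params <- function(theta_r, theta_s, alpha, n) {
  assert_number(theta_r, "theta_r", 0, 1)
  assert_number(theta_s, "theta_s", 0, 1)
  if (theta_r >= theta_s) stopf("vg_params(): need theta_r < theta_s")
  assert_number(alpha, "alpha", 0, strict_lower = TRUE)
  assert_number(n, "n", 1, strict_lower = TRUE)
  structure(list(theta_r = theta_r, theta_s = theta_s, alpha = alpha,
                 n = n, m = 1 - 1 / n), class = "vg_params")
}

#' Volumetric water content from the van Genuchten curve
#'
#' @param params A [vg_params()] object.
#' @param suction_cm Matric suction in cm of water, >= 0. Vectorised.
#' @return Volumetric water content in \[theta_r, theta_s\].
#' @export
vg_theta <- function(params, suction_cm) {
  if (!inherits(params, "vg_params"))
    stopf("vg_theta(): `params` must be a vg_params object")
  if (!all(is.finite(suction_cm)) || any(suction_cm < 0))
    stopf("vg_theta(): suction must be finite and >= 0")
  with(params,
       theta_r + (theta_s - theta_r) * (1 + (alpha * suction_cm)^n)^(-m))
}

#' Texture-class average van Genuchten parameters
#'
#' Lookup of class-average retention parameters by USDA texture class.
#' Values are the widely used class averages from neural-network
#' pedotransfer calibration on the US soils database (theta_r, theta_s in
#' cm^3 cm^-3; alpha in cm^-1; n dimensionless). Exported so users can
#' inspect or replace the table.
#'
#' @format Tibble with columns `class`, `theta_r`, `theta_s`, `alpha`, `n`.
#' @export
vg_class_table <- function() {
  tibble::tribble(
    ~class,            ~theta_r, ~theta_s, ~alpha,  ~n,
    "sand",            0.053,    0.375,    0.0353,  3.180,
    "loamy sand",      0.049,    0.390,    0.0347,  1.746,
    "sandy loam",      0.039,    0.387,    0.0267,  1.448,
    "loam",            0.061,    0.399,    0.0111,  1.474,
    "silt loam",       0.065,    0.439,    0.0051,  1.663,
    "silt",            0.050,    0.489,    0.0066,  1.679,
    "sandy clay loam", 0.063,    0.384,    0.0211,  1.330,
    "clay loam",       0.079,    0.442,    0.0158,  1.415,
    "silty clay loam", 0.090,    0.482,    0.0084,  1.520,
    "sandy clay",      0.117,    0.385,    0.0334,  1.208,
    "silty clay",      0.111,    0.481,    0.0162,  1.321,
    "clay",            0.098,    0.459,    0.0150,  1.253
  )
}

#' USDA texture-triangle classification
#'
#' Classifies a (sand, silt, clay) composition into one of the twelve USDA
#' texture classes using the standard triangle boundary rules.
#'
#' @param sand,silt,clay Mass fractions summing to 1 (tolerance 1e-6).
#' @return Class name (character scalar), matching [vg_class_table()].
#' @export
texture_class <- function(sand, silt, clay) {
  tot <- sand + silt + clay
  if (!is.finite(tot) || abs(tot - 1) > 1e-6)
    stopf("texture_class(): fractions must sum to 1 (got %.6f)", tot)
  if (sand < 0 || silt < 0 || clay < 0)
    stopf("texture_class(): fractions must be >= 0")
  sa <- sand * 100; si <- silt * 100; cl <- clay * 100
  if (si + 1.5 * cl < 15) return("sand")
  if (si + 2 * cl < 30) return("loamy sand")
  if (cl >= 40 && si >= 40) return("silty clay")
  if (cl >= 35 && sa > 45) return("sandy clay")
  if (cl >= 40 && sa <= 45 && si < 40) return("clay")
  if (cl >= 27 && cl < 40 && sa <= 20) return("silty clay loam")
  if (cl >= 27 && cl < 40 && sa > 20 && sa <= 45) return("clay loam")
  if (cl >= 20 && cl < 35 && si < 28 && sa > 45) return("sandy clay loam")
  if (si >= 80 && cl < 12) return("silt")
  if ((si >= 50 && cl >= 12 && cl < 27) || (si >= 50 && si < 80 && cl < 12))
    return("silt loam")
  if (cl >= 7 && cl < 27 && si >= 28 && si < 50 && sa <= 52) return("loam")
  "sandy loam"
}

#' Pedotransfer: texture to van Genuchten parameters
#'
#' Maps a soil composition to retention parameters through the shipped
#' texture-class lookup ([vg_class_table()]). The full neural-network
#' pedotransfer used to build such tables is not reproduced; externally
#' computed parameters can be supplied via `override` and are validated and
#' returned unchanged.
#'
#' @inheritParams texture_class
#' @param bulk_density Bulk density, g cm^-3 (currently unused by the
#'   class lookup; accepted for schema compatibility).
#' @param override Optional [vg_params()] object to use instead of the
#'   lookup.
#' @return A [vg_params()] object.
#' @export
texture_to_vg <- function(sand, silt, clay, bulk_density = NULL,
                          override = NULL) {
  if (!is.null(override)) {
    if (!inherits(override, "vg_params"))
      stopf("texture_to_vg(): `override` must be a vg_params object")
    return(override)
  }
  cls <- texture_class(sand, silt, clay)
  tab <- vg_class_table()
  row <- tab[tab$class == cls, ]
  vg_params(row$theta_r, row$theta_s, row$alpha, row$n)
}

#' Plant-available water capacity of a soil profile
#'
#' AWC is the water held between field capacity (pF 1.8, -60 hPa) and
#' permanent wilting point (pF 4.2, -1.5 MPa), integrated over the profile
#' and extrapolated to a standard depth (default 100 cm) by reusing the
#' deepest layer's retention parameters below its bottom, i.e. assuming a
#' homogeneous particle composition below the deepest sampled layer.
#'
#' @param profile Data frame with columns `top_cm`, `bottom_cm` (layers
#'   contiguous from 0) and optionally `stone_fraction`.
#' @param params_per_layer List of [vg_params()], one per profile row.
#' @param standard_depth_cm Depth to which AWC is integrated, cm.
#' @param pf_fc,pf_pwp pF at field capacity and permanent wilting point.
#' @param correct_stones If `TRUE`, each layer's AWC is multiplied by
#'   (1 - stone_fraction). Off by default.
#' @return Total AWC in mm.
#' @export
profile_awc <- function(profile, params_per_layer, standard_depth_cm = 100,
                        pf_fc = 1.8, pf_pwp = 4.2, correct_stones = FALSE) {
  if (!all(c("top_cm", "bottom_cm") %in% names(profile)))
    stopf("profile_awc(): profile needs top_cm and bottom_cm columns")
  o <- order(profile$top_cm)
  profile <- profile[o, , drop = FALSE]
  params_per_layer <- params_per_layer[o]
  if (length(params_per_layer) != nrow(profile))
    stopf("profile_awc(): one vg_params per layer required")
  if (profile$top_cm[1L] != 0)
    stopf("profile_awc(): layers must start at 0 cm")
  if (nrow(profile) > 1L &&
      any(abs(profile$top_cm[-1L] - profile$bottom_cm[-nrow(profile)]) > 1e-9))
    stopf("profile_awc(): layers must be contiguous (gap or overlap found)")

  # extrapolate: deepest layer's parameters fill down to standard depth
  deepest <- nrow(profile)
  if (profile$bottom_cm[deepest] < standard_depth_cm) {
    extra <- profile[deepest, , drop = FALSE]
    extra$top_cm <- profile$bottom_cm[deepest]
    extra$bottom_cm <- standard_depth_cm
    profile <- rbind(profile, extra)
    params_per_layer <- c(params_per_layer, params_per_layer[deepest])
  }
  profile$bottom_cm <- pmin(profile$bottom_cm, standard_depth_cm)
  keep <- profile$bottom_cm > profile$top_cm
  profile <- profile[keep, , drop = FALSE]
  params_per_layer <- params_per_layer[keep]

  # suction at the two reference potentials, in cm of water
  h_fc <- (10^pf_fc) * CM_PER_HPA
  h_pwp <- (10^pf_pwp) * CM_PER_HPA
  awc <- 0
  for (i in seq_len(nrow(profile))) {
    p <- params_per_layer[[i]]
    d_theta <- vg_theta(p, h_fc) - vg_theta(p, h_pwp)
    thick_cm <- profile$bottom_cm[i] - profile$top_cm[i]
    layer_mm <- d_theta * thick_cm * 10
    if (correct_stones && "stone_fraction" %in% names(profile))
      layer_mm <- layer_mm * (1 - profile$stone_fraction[i])
    awc <- awc + layer_mm
  }
  awc
}
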