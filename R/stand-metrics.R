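#' Hegyi competition index
#'
#' Size-ratio-over-distance competition index for a target tree \eqn{i}:
#' \deqn{CI_i = \sum_j \frac{d_j / d_i}{Dist_{ij}},}
#' where \eqn{d} are stem diameters at breast height (cm) and
#' \eqn{Dist_{ij}} the horizontal distance to competitor \eqn{j} (m). The
#' sum runs over the supplied competitor set, conventionally the three
#' nearest neighbours (see [nearest_neighbours()]).
#'
#' @param dbh_target DBH of the target tree, cm, > 0.
#' @param dbh_neighbours Numeric vector of competitor DBH values, cm.
#' @param distances Numeric vector of target-competitor distances, m, > 0.
#' @return Dimensionless competition index.
#' @export
hegyi_index <- function(dbh_target, dbh_neighbours, distances) {
  assert_number(dbh_target, "dbh_target", 0, strict_lower = TRUE)
  if (length(dbh_neighbours) != length(distances))
    stopf("hegyi_index(): neighbour DBH and distance lengths differ")
  if (length(dbh_neighbours) == 0L)
    stopf("hegyi_index(): at least one neighbour required")
  if (any(!is.finite(distances)) || any(distances <= 0))
    stopf("hegyi_index(): distances must be finite and > 0")
  if (any(!is.finite(dbh_neighbours)) || any(dbh_neighbours <= 0))
    stopf("hegyi_index(): neighbour DBH must be finite and > 0")
  sum((dbh_neighbours / dbh_target) / distances)
}

#' Nearest neighbours in a stand map
#'
#' Selects the `n` nearest trees to each target tree by Euclidean distance
#' from stand-map coordinates; distance ties are broken by `tree_id` order.
#'
#' @param trees Data frame with columns `tree_id`, `x`, `y`, `dbh`.
#' @param target_ids Tree ids to resolve neighbours for (default: all).
#' @param n Number of neighbours (default 3).
#' @return Tibble with columns `tree_id`, `neighbour_id`, `dbh_neighbour`,
#'   `distance`, `rank`.
#' @export
nearest_neighbours <- function(trees, target_ids = trees$tree_id, n = 3L) {
  need <- c("tree_id", "x", "y", "dbh")
  miss <- setdiff(need, names(trees))
  if (length(miss))
    stopf("nearest_neighbours(): missing columns: %s",
          paste(miss, collapse = ", "))
  out <- lapply(target_ids, function(id) {
    i <- match(id, trees$tree_id)
    if (is.na(i)) stopf("nearest_neighbours(): unknown tree_id %s", id)
    dx <- trees$x - trees$x[i]; dy <- trees$y - trees$y[i]
    d <- sqrt(dx^2 + dy^2)
    others <- setdiff(seq_len(nrow(trees)), i)
    if (length(others) < n)
      stopf("nearest_neighbours(): tree %s has only %d potential neighbours (need %d)",
            id, length(others), n)
    if (any(d[others] == 0))
      stopf("nearest_neighbours(): zero distance between tree %s and another tree",
            id)
    ord <- others[order(d[others], trees$tree_id[others])][seq_len(n)]
    tibble::tibble(tree_id = id, neighbour_id = trees$tree_id[ord],
                   dbh_neighbour = trees$dbh[ord], distance = d[ord],
                   rank = seq_len(n))
  })
  do.call(rbind, out)
}

# Minimum branch cross-sectional area (mm^2) with positive xylem area
# under the shipped allometry.
XYLEM_AREA_INTERCEPT <- -3.715
XYLEM_AREA_SLOPE <- 0.770

#' Xylem cross-sectional area from branch cross-sectional area
#'
#' Linear allometry relating the xylem area without pith and bark
#' (\eqn{A_{xylem}}, mm^2) to the full branch cross-sectional area
#' (\eqn{A_{cross}}, mm^2):
#' \deqn{A_{xylem} = -3.715 + 0.770 \, A_{cross}.}
#' Inputs at or below the zero crossing (about 4.825 mm^2) are rejected.
#'
#' @param a_cross Branch cross-sectional area, mm^2. Vectorised.
#' @return Xylem cross-sectional area, mm^2, > 0.
#' @export
xylem_area <- function(a_cross) {
  if (!all(is.finite(a_cross))) stopf("xylem_area(): a_cross must be finite")
  out <- XYLEM_AREA_INTERCEPT + XYLEM_AREA_SLOPE * a_cross
  if (any(out <= 0)) {
    amin <- -XYLEM_AREA_INTERCEPT / XYLEM_AREA_SLOPE
    stopf("xylem_area(): a_cross must exceed %.4f mm^2 for a positive xylem area",
          amin)
  }
  out
}

# Single site of the mm^2 -> m^2 conversion used for conductivity scaling.
MM2_TO_M2 <- 1e-6

#' Specific conductivity
#'
#' Maximum (flushed) hydraulic conductivity \eqn{K_h}
#' (kg m MPa^-1 s^-1) divided by the xylem cross-sectional area, giving the
#' xylem-specific conductivity \eqn{K_s} (kg m^-1 MPa^-1 s^-1).
#'
#' @param max_kh Maximum hydraulic conductivity after flushing,
#'   kg m MPa^-1 s^-1, >= 0.
#' @param a_xylem_mm2 Xylem cross-sectional area, mm^2, > 0.
#' @return Specific conductivity, kg m^-1 MPa^-1 s^-1.
#' @export
specific_conductivity <- function(max_kh, a_xylem_mm2) {
  if (!all(is.finite(max_kh)) || any(max_kh < 0))
    stopf("specific_conductivity(): max_kh must be finite and >= 0")
  if (!all(is.finite(a_xylem_mm2)) || any(a_xylem_mm2 <= 0))
    stopf("specific_conductivity(): xylem area must be > 0")
  max_kh / (a_xylem_mm2 * MM2_TO_M2)
}

#' Mean branch age from ring counts
#'
#' Age of a branch segment estimated as the arithmetic mean of the growth
#' ring counts at its basipetal (older) and acropetal (younger) ends;
#' half-integer results are meaningful. Counts where the acropetal end is
#' older than the basipetal end violate branch growth direction and are
#' rejected.
#'
#' @param rings_basipetal,rings_acropetal Ring counts, integers >= 1.
#'   Vectorised.
#' @return Mean branch age in years.
#' @export
mean_branch_age <- function(rings_basipetal, rings_acropetal) {
  if (any(!is.finite(rings_basipetal)) || any(!is.finite(rings_acropetal)))
    stopf("mean_branch_age(): ring counts must be finite")
  if (any(rings_basipetal < 1) || any(rings_acropetal < 1))
    stopf("mean_branch_age(): ring counts must be >= 1")
  if (any(rings_acropetal > rings_basipetal))
    stopf("mean_branch_age(): acropetal ring count exceeds basipetal; age cannot increase toward the tip")
  (rings_basipetal + rings_acropetal) / 2
}

#' Tree-level covariate table
#'
#' Joins stand geometry, branch measurements and site water metrics into
#' the covariate table consumed by the trait models: Hegyi competition
#' index from the stand map, mean branch age from ring counts, specific
#' conductivity from flushed conductivity and the xylem-area allometry
#' (circular cross-section from the basipetal diameter), plus site CWB and
#' AWC and tree height.
#'
#' @param trees Tree table (`tree_id`, `site_id`, `dbh`, `height`, `x`,
#'   `y`, optional `is_sample`).
#' @param branches Branch table (`branch_id`, `tree_id`,
#'   `basipetal_diameter_mm`, `rings_basipetal`, `rings_acropetal`,
#'   `max_kh`).
#' @param sites Site table (`site_id`, `cwb`, `awc`).
#' @param n_neighbours Competitor count for the Hegyi index.
#' @return Tibble keyed by `tree_id` with `site_id`, `branch_id`, `cwb`,
#'   `awc`, `height`, `branch_age`, `ci`, `ks`.
#' @export
compute_tree_covariates <- function(trees, branches, sites,
                                    n_neighbours = 3L) {
  sample_ids <- if ("is_sample" %in% names(trees))
    trees$tree_id[trees$is_sample] else trees$tree_id

  ci <- vapply(sample_ids, function(id) {
    site <- trees$site_id[match(id, trees$tree_id)]
    stand <- trees[trees$site_id == site, , drop = FALSE]
    nb <- nearest_neighbours(stand, target_ids = id, n = n_neighbours)
    hegyi_index(stand$dbh[match(id, stand$tree_id)],
                nb$dbh_neighbour, nb$distance)
  }, numeric(1))

  b <- branches[match(sample_ids, branches$tree_id), , drop = FALSE]
  if (any(is.na(b$branch_id)))
    stopf("compute_tree_covariates(): no branch for tree(s) %s",
          paste(sample_ids[is.na(b$branch_id)], collapse = ", "))
  a_cross <- pi * (b$basipetal_diameter_mm / 2)^2
  a_xyl <- xylem_area(a_cross)
  ks <- specific_conductivity(b$max_kh, a_xyl)
  age <- mean_branch_age(b$rings_basipetal, b$rings_acropetal)

  si <- match(trees$site_id[match(sample_ids, trees$tree_id)], sites$site_id)
  tibble::tibble(
    tree_id = sample_ids,
    site_id = sites$site_id[si],
    branch_id = b$branch_id,
    cwb = sites$cwb[si],
    awc = sites$awc[si],
    height = trees$height[match(sample_ids, trees$tree_id)],
    branch_age = age,
    ci = unname(ci),
    ks = ks)
}
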