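#' Write a study to CSV tables
#'
#' Writes the pipeline's on-disk schema: `sites.csv`, `trees.csv`
#' (sampled trees), `stand.csv` (full stand maps), `branches.csv`,
#' `soil.csv`, `climate.csv`, one `cavitron/<branch_id>.csv` per series
#' (columns `branch_id`, `pressure_MPa`, `conductivity`), and a plain
#' key-value `metadata.txt` recording the seed and design.
#'
#' @param study A `synthetic_study` (or compatible list of tables).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "cavitron"), showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(study$site_table, "sites.csv")
  wr(study$tree_table, "trees.csv")
  if (!is.null(study$stand_table)) wr(study$stand_table, "stand.csv")
  wr(study$branch_table, "branches.csv")
  wr(study$soil_table, "soil.csv")
  wr(study$climate_table, "climate.csv")
  for (id in names(study$cavitron)) {
    s <- study$cavitron[[id]]
    wr(data.frame(branch_id = id, pressure_MPa = s$pressure,
                  conductivity = s$conductivity),
       file.path("cavitron", paste0(id, ".csv")))
  }
  meta <- c(
    sprintf("seed: %d", study$config$seed),
    sprintf("n_sites: %d", study$config$n_sites),
    sprintf("n_trees_per_site: %d", study$config$n_trees_per_site),
    sprintf("noise_cv: %g", study$config$noise_cv),
    sprintf("pressure_step: %g", study$config$pressure_step))
  writeLines(meta, file.path(dir, "metadata.txt"))
  paths <- c(paths, file.path(dir, "metadata.txt"))
  invisible(paths)
}

#' Read a study from CSV tables
#'
#' Inverse of [write_study()]: reads the table schema back into a list
#' usable by [run_pipeline()].
#'
#' @param dir Directory containing the CSV tables.
#' @return List of tables plus a `cavitron` list of [cavitron_series()].
#' @export
read_study <- function(dir) {
  rd <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) stopf("read_study(): missing %s", p)
    tibble::as_tibble(read.csv(p, stringsAsFactors = FALSE))
  }
  out <- list(site_table = rd("sites.csv"), tree_table = rd("trees.csv"),
              branch_table = rd("branches.csv"), soil_table = rd("soil.csv"),
              climate_table = rd("climate.csv"))
  if (file.exists(file.path(dir, "stand.csv")))
    out$stand_table <- rd("stand.csv")
  cav_files <- list.files(file.path(dir, "cavitron"), pattern = "\\.csv$",
                          full.names = TRUE)
  out$cavitron <- lapply(cav_files, function(p) {
    d <- read.csv(p, stringsAsFactors = FALSE)
    cavitron_series(d$branch_id[1L], d$pressure_MPa, d$conductivity)
  })
  names(out$cavitron) <- vapply(out$cavitron, attr, character(1), "branch_id")
  out
}

#' Validate pipeline input tables
#'
#' Schema, unit-range and referential-integrity checks: every branch must
#' reference a known tree and every tree a known site; cavitron pressures
#' must be negative and conductivities non-negative; soil fractions must
#' sum to one. All violations are collected, not just the first.
#'
#' @param tables List with `site_table`, `tree_table`, `branch_table`, and
#'   optionally `cavitron`, `soil_table`, `climate_table`.
#' @return Tibble of violations (`table`, `id`, `problem`); zero rows when
#'   clean.
#' @export
validate_inputs <- function(tables) {
  v <- list()
  add <- function(tab, id, problem)
    v[[length(v) + 1L]] <<- tibble::tibble(table = tab, id = as.character(id),
                                           problem = problem)

  tr <- tables$tree_table; si <- tables$site_table; br <- tables$branch_table
  if (is.null(si) || is.null(tr) || is.null(br))
    stopf("validate_inputs(): site, tree and branch tables are required")
  bad <- !tr$site_id %in% si$site_id
  for (id in tr$tree_id[bad]) add("trees", id, "references unknown site_id")
  bad <- !br$tree_id %in% tr$tree_id
  for (id in br$branch_id[bad]) add("branches", id, "references unknown tree_id")
  for (id in tr$tree_id[tr$dbh <= 0]) add("trees", id, "non-positive dbh")
  for (id in tr$tree_id[tr$height <= 0]) add("trees", id, "non-positive height")
  if (all(c("rings_basipetal", "rings_acropetal") %in% names(br))) {
    bad <- br$rings_acropetal > br$rings_basipetal
    for (id in br$branch_id[bad])
      add("branches", id, "acropetal ring count exceeds basipetal")
  }
  for (s in tables$cavitron) {
    id <- attr(s, "branch_id")
    if (any(s$pressure >= 0)) add("cavitron", id, "non-negative pressure")
    if (any(s$conductivity < 0)) add("cavitron", id, "negative conductivity")
    if (!id %in% br$branch_id) add("cavitron", id, "references unknown branch_id")
  }
  so <- tables$soil_table
  if (!is.null(so)) {
    bad <- abs(so$sand + so$silt + so$clay - 1) > 1e-6
    for (id in so$site_id[bad])
      add("soil", id, "texture fractions do not sum to 1")
  }
  cl <- tables$climate_table
  if (!is.null(cl)) {
    if (any(cl$precip_mm < 0)) add("climate", "-", "negative precipitation")
    if (any(cl$pet_mm < 0)) add("climate", "-", "negative PET")
    if (any(!cl$month %in% 1:12)) add("climate", "-", "month outside 1-12")
  }
  if (length(v)) do.call(rbind, v) else
    tibble::tibble(table = character(), id = character(),
                   problem = character())
}

#' Fit vulnerability curves for every series in a study
#'
#' @param cavitron Named list of [cavitron_series()].
#' @param seed Seed for fit restarts.
#' @return Tibble with one row per branch: parameter estimates, standard
#'   errors, derived P12/P88, convergence flag and RSS.
#' @export
fit_all_curves <- function(cavitron, seed = 1L) {
  rows <- lapply(cavitron, function(s) {
    f <- fit_vulnerability_curve(s, seed = seed)
    tibble::tibble(
      branch_id = f$branch_id, kmax = f$kmax, p50 = f$p50, slope = f$slope,
      p12 = f$p12, p88 = f$p88, se_kmax = f$se[["kmax"]],
      se_p50 = f$se[["p50"]], se_slope = f$se[["slope"]],
      converged = f$converged, reason = f$reason, rss = f$rss, n = f$n)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: obtain a study (synthetic via
#' [simulate_study()] or read from `input_dir`), validate it, fit a
#' vulnerability curve per branch, assemble tree-level covariates (site
#' CWB/AWC, height, branch age, Hegyi CI, Ks), join fitted traits, fit the
#' five random-intercept trait models, and report variance fractions. The
#' run is deterministic given the seed; a manifest records row counts,
#' warnings (non-converged fits, dropped rows, singular fits) and, when
#' `out_dir` is given, md5 checksums of every written table.
#'
#' @param config A [study_config()] for a synthetic run (ignored when
#'   `input_dir` is given). One of `config`/`input_dir` is required.
#' @param input_dir Directory of CSV inputs in the [write_study()] schema.
#' @param out_dir Optional output directory for result CSVs.
#' @param seed Pipeline seed (defaults to the config seed).
#' @return List with `fits`, `covariates`, `traits`, `models`
#'   (named `lmm_result` list), `variance_table`, `coefficient_table`,
#'   `correlations`, and `manifest`.
#' @export
run_pipeline <- function(config = NULL, input_dir = NULL, out_dir = NULL,
                         seed = NULL) {
  if (is.null(config) && is.null(input_dir))
    stopf("run_pipeline(): provide a study_config or an input_dir")
  warnings <- character()

  if (!is.null(input_dir)) {
    study <- read_study(input_dir)
    if (is.null(seed)) seed <- 1L
  } else {
    if (is.null(seed)) seed <- config$seed
    config$seed <- as.integer(seed)
    study <- simulate_study(config)
  }

  viol <- validate_inputs(study)
  if (nrow(viol))
    stopf("run_pipeline(): validation failed (%d violations), e.g. %s %s: %s",
          nrow(viol), viol$table[1L], viol$id[1L], viol$problem[1L])

  fits <- fit_all_curves(study$cavitron,
                         seed = child_seed(seed, "fit"))
  n_nonconv <- sum(!fits$converged)
  if (n_nonconv)
    warnings <- c(warnings,
                  sprintf("%d vulnerability fits did not converge", n_nonconv))

  trees <- study$tree_table
  if (!is.null(study$stand_table)) {
    stand <- study$stand_table
  } else {
    stand <- trees
    stand$is_sample <- TRUE
  }
  if (!"is_sample" %in% names(stand))
    stand$is_sample <- stand$tree_id %in% trees$tree_id
  covariates <- compute_tree_covariates(stand, study$branch_table,
                                        study$site_table)

  traits <- merge(covariates,
                  fits[fits$converged,
                       c("branch_id", "p12", "p50", "p88", "slope")],
                  by = "branch_id", all.x = TRUE)
  traits <- tibble::as_tibble(traits)

  models_out <- fit_trait_models(traits)
  if (models_out$n_dropped)
    warnings <- c(warnings, sprintf("%d trait rows dropped listwise",
                                    models_out$n_dropped))
  singular <- names(models_out$models)[vapply(models_out$models,
                                              function(m) m$singular,
                                              logical(1))]
  if (length(singular))
    warnings <- c(warnings, sprintf("singular fit(s): %s",
                                    paste(singular, collapse = ", ")))

  screen <- correlation_screen(
    traits, columns = c("cwb", "awc", "height", "branch_age", "ci"))

  coefficient_table <- do.call(rbind, lapply(models_out$models, function(m)
    cbind(response = m$response, as.data.frame(m$coefficients))))
  variance_table <- do.call(rbind, lapply(models_out$models, function(m)
    data.frame(response = m$response,
               fixed = m$variance_fractions[["fixed"]],
               site = m$variance_fractions[["site"]],
               residual = m$variance_fractions[["residual"]],
               site_sd = m$site_sd, residual_sd = m$residual_sd,
               marginal_r2 = m$marginal_r2,
               conditional_r2 = m$conditional_r2)))
  rownames(coefficient_table) <- rownames(variance_table) <- NULL

  checksums <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(fits = "fits.csv", covariates = "covariates.csv",
               traits = "traits.csv", coefficients = "coefficients.csv",
               variance = "variance_fractions.csv")
    objs <- list(fits, covariates, traits, coefficient_table, variance_table)
    for (i in seq_along(files))
      write.csv(objs[[i]], file.path(out_dir, files[i]), row.names = FALSE)
    checksums <- tools::md5sum(file.path(out_dir, files))
    names(checksums) <- files
  }

  manifest <- list(
    seed = seed,
    counts = c(sites = nrow(study$site_table), trees = nrow(trees),
               branches = nrow(study$branch_table),
               series = length(study$cavitron),
               fits_converged = sum(fits$converged),
               fits_failed = n_nonconv,
               trait_rows = nrow(traits),
               rows_dropped = models_out$n_dropped),
    warnings = warnings,
    collinearity_flags = nrow(screen$flagged),
    checksums = checksums)

  list(fits = fits, covariates = covariates, traits = traits,
       models = models_out$models, scaling = models_out$scaling,
       coefficient_table = tibble::as_tibble(coefficient_table),
       variance_table = tibble::as_tibble(variance_table),
       correlations = screen, manifest = manifest)
}
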