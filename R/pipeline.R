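#' Default pipeline configuration
#'
#' All stage parameters of the end-to-end analysis with their defaults:
#' collinearity cutoff `rho_max` 0.75, 10 equal-interval bias bins, 1000
#' null replicates, sample-size keyed threshold rules, cluster numbers
#' 2-30 scored on five 1000-cell subsamples, NMDS with 100 starts,
#' vector fitting at P < 0.001 with 999 permutations, and a factor-2
#' environmental coarsening for the Gi* table.  Values can be overridden
#' and the configuration round-trips through YAML.
#'
#' @param ... named overrides of any default.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    min_cells = 5,
    rho_max = 0.75,
    predictor_priority = NULL,
    bias_bins = 10,
    bias_alpha = 0.05,
    n_null = 1000,
    regularization_multiplier = 1,
    threshold_rule = NULL,       # NULL = auto by sample size
    k_range = 2:30,
    subsample_size = 1000,
    n_repeats = 5,
    indval_perm = 999,
    nmds_starts = 100,
    nmds_max_cells = 1000,
    envfit_perm = 999,
    envfit_alpha = 0.001,
    coarsen_factor = 2,
    simulate = list(n_lon = 40, n_lat = 30, n_predictors = 8,
                    n_species = 200, k_regions = 4, effort = 5000,
                    bias_strength = 0)
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config` the
#'   configuration (round-trips exactly).
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on a synthetic world: simulate, prune
#' predictors, diagnose collection bias, fit and null-test all SDMs,
#' stack the significant species, explain richness (variation
#' partitioning, stepwise regression, residual Moran's I), regionalize
#' (beta-sim + UPGMA + indicator-species k selection) and characterize
#' relative environmental turnover (NMDS + vector fitting + Gi*).  Every
#' artifact is written to `outdir` as plain text together with a manifest
#' recording the seed and parameters; a rerun with the same configuration
#' reproduces the outputs bit for bit.
#'
#' @param cfg a [pipeline_config()] (or path to a YAML config).
#' @param outdir output directory.
#' @return (invisibly) a list with all stage results.
#' @export
run_pipeline <- function(cfg = pipeline_config(), outdir) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- child_seeds(cfg$seed, 8)
  log_stage <- function(fmt, ...) {
    message(sprintf(paste0("[pipeline] ", fmt), ...))
  }

  log_stage("simulating world (seed %s)", cfg$seed)
  sim <- cfg$simulate
  world <- simulate_world(
    n_lon = sim$n_lon, n_lat = sim$n_lat, n_predictors = sim$n_predictors,
    n_species = sim$n_species, k_regions = sim$k_regions,
    seed = seeds[[1]])
  occ <- collect_records(world, effort = sim$effort,
                         bias_strength = sim$bias_strength,
                         seed = seeds[[2]])
  occ <- occurrences_from_records(as_tibble(occ), world$grid,
                                  min_cells = cfg$min_cells)
  write_occurrences(occ, world$grid, file.path(outdir, "occurrences.csv"))

  log_stage("pruning predictors (rho_max %.2f)", cfg$rho_max)
  env <- prune_predictors(world$env, rho_max = cfg$rho_max,
                          priority = cfg$predictor_priority)
  write.csv(attr(env, "dropped"), file.path(outdir, "pruned_predictors.csv"),
            row.names = FALSE)

  log_stage("bias test over %d localities",
            length(collection_localities(occ)))
  bias <- bias_test(env, collection_localities(occ),
                    n_bins = cfg$bias_bins, alpha = cfg$bias_alpha)
  write.csv(as_tibble(bias), file.path(outdir, "bias_report.csv"),
            row.names = FALSE)

  log_stage("fitting and null-testing %d species",
            dplyr::n_distinct(occ$species))
  screen <- null_model_screen(occ, env, n_null = cfg$n_null,
                              regularization_multiplier =
                                cfg$regularization_multiplier,
                              seed = seeds[[3]])
  write.csv(screen$tests, file.path(outdir, "null_tests.csv"),
            row.names = FALSE)
  keep <- screen$tests$species[screen$tests$significant]
  if (length(keep) < 2) abort("fewer than two species pass the null test")

  log_stage("stacking %d significant species", length(keep))
  pa <- stack_sdms(screen$fits[keep], rules = cfg$threshold_rule,
                   grid = world$grid)
  write_matrix(pa$pa, file.path(outdir, "presence_absence.txt"),
               format = "sparse")
  write.csv(pa$thresholds, file.path(outdir, "thresholds.csv"),
            row.names = FALSE)
  rich <- richness(pa)
  write.csv(rich, file.path(outdir, "richness.csv"), row.names = FALSE)
  grid_to_ascii(world$grid, rich$richness,
                file.path(outdir, "richness.asc"))

  log_stage("richness drivers")
  space <- trend_surface_terms(world$grid)
  part <- variation_partition(rich, env, space)
  model <- stepwise_regression(rich, env)
  resid_mi <- if (!is.null(model$model)) {
    morans_i(stats::residuals(model$model), world$grid)
  } else NULL
  write.csv(tidy(model), file.path(outdir, "stepwise_model.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(partition = as.list(part),
         residual_morans_i = if (!is.null(resid_mi)) as.list(resid_mi)),
    file.path(outdir, "richness_drivers.json"), auto_unbox = TRUE,
    digits = NA)

  log_stage("regionalization (k in %d..%d)", min(cfg$k_range),
            max(cfg$k_range))
  d <- dissimilarity_matrix(pa)
  reg <- optimal_k(pa, d = d, k_range = cfg$k_range,
                   subsample_size = cfg$subsample_size,
                   n_repeats = cfg$n_repeats, n_perm = cfg$indval_perm,
                   seed = seeds[[4]])
  write.csv(reg$labels, file.path(outdir, "regions.csv"), row.names = FALSE)
  write.csv(reg$mean_curve, file.path(outdir, "summed_p_curve.csv"),
            row.names = FALSE)
  write_newick(reg$dendrogram, file.path(outdir, "dendrogram.nwk"))

  log_stage("ordination and relative environmental turnover")
  cells <- rownames(unclass(d))
  if (length(cells) > cfg$nmds_max_cells) {
    idx <- with_seed(seeds[[5]],
                     sort(sample(length(cells), cfg$nmds_max_cells)))
    dn <- unclass(d)[idx, idx]
  } else {
    dn <- unclass(d)
  }
  ord <- nmds_ordination(dn, n_starts = cfg$nmds_starts, seed = seeds[[6]])
  vec <- fit_env_vectors(ord, env, n_perm = cfg$envfit_perm,
                         alpha = cfg$envfit_alpha, seed = seeds[[7]])
  gi <- ret_table(reg, env, world$grid, factor = cfg$coarsen_factor)
  write.csv(cbind(cell_id = rownames(ord$scores), as.data.frame(ord$scores)),
            file.path(outdir, "nmds_scores.csv"), row.names = FALSE)
  write.csv(vec, file.path(outdir, "env_vectors.csv"), row.names = FALSE)
  write.csv(as_tibble(gi), file.path(outdir, "gi_star.csv"),
            row.names = FALSE)

  yaml::write_yaml(list(seed = cfg$seed, config = unclass(cfg),
                        stress = ord$stress, chosen_k = reg$k),
                   file.path(outdir, "manifest.yml"))
  invisible(list(world = world, occurrences = occ, env = env, bias = bias,
                 screen = screen, pa = pa, richness = rich,
                 partition = part, model = model, moran = resid_mi,
                 regionalization = reg, ordination = ord, vectors = vec,
                 gi_star = gi))
}
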