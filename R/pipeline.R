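default_pipeline_config <- function() {
  list(
    simulate = list(n_population_sites = 1000, n_sampled_sites = 150,
                    n_nonprobability_sites = 25),
    qc = list(rel_diff_max = 0.40, bd_max = 2.0),
    bd_model = list(enabled = TRUE, n_trees = 600, shrinkage = 0.05,
                    max_tree_depth = 5, bag_fraction = 0.5,
                    train_fraction = 0.70),
    estimation = list(target_area_Mha = NA_real_),
    disturbance = list(target_most_fraction = 0.25, least_quantile = 0.50)
  )
}

read_pipeline_config <- function(config) {
  if (is.null(config)) return(default_pipeline_config())
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  utils::modifyList(default_pipeline_config(), config)
}

#' Run the full accounting pipeline on synthetic or supplied data
#'
#' Orchestrates one reproducible run: simulate (or read) the survey
#' tables, impute missing carbon, fit the bulk density model on measured
#' horizons and screen/fill bulk density, slice profiles and compute
#' per-site depth-range densities, classify soils, calibrate and apply
#' the disturbance screen, and produce design-based subpopulation
#' estimates. Stage outputs are written as CSV/JSON files into `out_dir`
#' so a run can be inspected and re-run; a manifest records the seed,
#' config hash, and row counts at each stage. Output is a pure function
#' of (inputs, config, seed).
#'
#' @param config `NULL` for defaults, a named list, or the path to a
#'   YAML/JSON config file with any of the blocks `simulate` (or
#'   `inputs` with `sites`/`horizons` paths), `qc`, `bd_model`,
#'   `estimation`, `disturbance`.
#' @param out_dir run directory (created if needed).
#' @param seed master seed for simulation and model fitting.
#' @return invisibly, a list with `sites`, `horizons`, `per_site`,
#'   `estimates`, `bd_fit`, `thresholds`, `manifest`.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("wetcarbon_run_"),
                         seed = 1) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  ## inputs: simulate or read
  if (!is.null(cfg$inputs)) {
    sites <- read_sites(cfg$inputs$sites)
    horizons <- read_horizons(cfg$inputs$horizons)
    truth <- NULL
  } else {
    sim_cfg <- simulation_config(
      seed = seed,
      n_population_sites = cfg$simulate$n_population_sites,
      n_sampled_sites = cfg$simulate$n_sampled_sites)
    sim <- generate_population(sim_cfg)
    sampled <- sample_survey(
      sim, seed = seed + 1,
      n_nonprobability = cfg$simulate$n_nonprobability_sites)
    sites <- sampled
    horizons <- sim$horizons[sim$horizons$site_id %in% sites$site_id, ]
    truth <- sim$truth
    write_sites(sites, file.path(out_dir, "sites.csv"))
    write_horizons(horizons, file.path(out_dir, "horizons.csv"))
    jsonlite::write_json(truth$totals, file.path(out_dir, "truth.json"),
                         digits = NA)
  }
  counts$sites <- nrow(sites)
  counts$horizons <- nrow(horizons)

  ## QC stage 1: carbon imputation
  imp <- impute_missing_carbon(horizons)
  unusable <- attr(imp$report, "unusable_sites")
  horizons <- imp$horizons[!imp$horizons$site_id %in% unusable, ]
  counts$horizons_after_carbon_qc <- nrow(horizons)

  ## bulk density model + screen
  bd_fit <- NULL
  bd_report <- NULL
  if (isTRUE(cfg$bd_model$enabled)) {
    spec <- bd_model_spec(n_trees = cfg$bd_model$n_trees,
                          shrinkage = cfg$bd_model$shrinkage,
                          max_tree_depth = cfg$bd_model$max_tree_depth,
                          bag_fraction = cfg$bd_model$bag_fraction,
                          train_fraction = cfg$bd_model$train_fraction,
                          seed = seed)
    bd_fit <- fit_bd_model(horizons, sites, spec, bd_max = cfg$qc$bd_max)
    pred <- predict_bd(bd_fit, horizons, sites)
    scr <- screen_bulk_density(horizons, pred,
                               rel_diff_max = cfg$qc$rel_diff_max,
                               bd_max = cfg$qc$bd_max)
    horizons <- scr$horizons
    bd_report <- scr$report
  } else if (anyNA(horizons$bd_g_cm3)) {
    stop(paste("bd_model is disabled but the horizon table still has",
               "missing bulk density; enable the model or supply complete",
               "measurements"), call. = FALSE)
  }

  ## accounting
  per_site <- site_depth_densities(horizons)
  counts$sites_accounted <- nrow(per_site)

  ## classification + disturbance screen
  soil <- classify_soil_sites(horizons, sites)
  thresholds <- calibrate_thresholds(
    sites, target_fraction = cfg$disturbance$target_most_fraction,
    least_quantile = cfg$disturbance$least_quantile, pool_sparse = TRUE)
  screened <- screen_sites(sites, thresholds)

  site_cols <- dplyr::select(screened, "site_id", "region",
                             "weight_ha", "probability_site",
                             "tidal_saline", "disturbance_class")
  per_site <- per_site |>
    dplyr::left_join(site_cols, by = "site_id") |>
    dplyr::left_join(soil, by = "site_id") |>
    dplyr::mutate(carbon_type = carbon_type(.data$tidal_saline))

  ## estimation: probability sites only
  est_data <- per_site[per_site$probability_site, ]
  estimates <- estimate_all(est_data)
  if (is.finite(cfg$estimation$target_area_Mha)) {
    nat <- estimates[estimates$grouping == "national", ]
    inference_area <- nat$area_Mha[which.max(nat$n_sites)]
    target_est <- scale_to_target(estimates, inference_area,
                                  cfg$estimation$target_area_Mha)
    write_estimates(target_est, file.path(out_dir, "estimates_target.csv"))
  }

  ## outputs
  readr::write_csv(per_site, file.path(out_dir, "per_site.csv"), na = "")
  write_estimates(estimates, file.path(out_dir, "estimates.csv"))
  readr::write_csv(thresholds, file.path(out_dir, "thresholds.csv"), na = "")
  qc_json <- list(carbon = imp$report, bulk_density = bd_report,
                  unusable_sites = unusable)
  jsonlite::write_json(qc_json, file.path(out_dir, "qc_report.json"),
                       digits = NA, null = "null")
  metrics <- list(
    gradient = gradient_summary(screened$disturbance_class),
    bd_holdout_r2 = if (!is.null(bd_fit)) bd_fit$holdout_r2 else NULL,
    bd_importance = if (!is.null(bd_fit)) as.list(bd_fit$importance)
                    else NULL)
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  config_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, config_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    package_version = as.character(utils::packageVersion("wetcarbon")),
    r_version = as.character(getRversion()),
    seed = seed,
    config_hash = unname(tools::md5sum(config_path)),
    row_counts = counts,
    created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(sites = screened, horizons = horizons,
                 per_site = per_site, estimates = estimates,
                 bd_fit = bd_fit, thresholds = thresholds,
                 truth = truth, manifest = manifest, out_dir = out_dir))
}
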