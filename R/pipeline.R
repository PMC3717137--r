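# End-to-end orchestration: simulate -> inventory -> calibrate -> upscale ->
# errors -> validate, from one configuration, with derived per-stage seeds
# and a reproducible run manifest.

#' Default pipeline configuration
#'
#' @param out_dir output directory for all stage artifacts.
#' @param seed global seed; each stage derives its own seed from it.
#' @param landscape a [landscape_config()] (its seed is overridden by the
#'   derived stage seed).
#' @param n_plots calibration + validation inventory size.
#' @param stride,n_trees ensemble ingestion stride and forest size.
#' @param spacing,swath transect geometry (cells).
#' @param overwrite_lidar keep direct LiDAR ACD on sampled cells of the
#'   national map.
#' @param stages character vector of stages to run, in order, from:
#'   simulate, inventory, calibrate, stratify, ensemble, errors, validate.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("carbonscape_run_"),
                       seed = 1L,
                       landscape = landscape_config(),
                       n_plots = 60,
                       stride = 10, n_trees = 500,
                       spacing = 25, swath = 1,
                       overwrite_lidar = FALSE,
                       stages = c("simulate", "inventory", "calibrate",
                                  "stratify", "ensemble", "errors",
                                  "validate")) {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), landscape = landscape,
         n_plots = n_plots, stride = stride, n_trees = n_trees,
         spacing = spacing, swath = swath,
         overwrite_lidar = overwrite_lidar, stages = stages),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys mirror [run_config()] arguments,
#'   with `landscape:` holding [landscape_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ls_args <- y$landscape %||% list()
  if (!is.null(ls_args$covariate_effects))
    ls_args$covariate_effects <- unlist(ls_args$covariate_effects)
  y$landscape <- do.call(landscape_config, ls_args)
  do.call(run_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 11L, inventory = 23L, calibrate = 37L,
               stratify = 41L, ensemble = 53L, errors = 67L, validate = 71L)
  (config$seed * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

log_stage <- function(stage, msg, verbose) {
  if (verbose) message(sprintf("[%s] %s", stage, msg))
}

#' Run the carbon-mapping pipeline end to end
#'
#' Executes the enabled stages in order on a synthetic landscape: simulate
#' the landscape; generate and analyse plot inventories; calibrate the
#' TCH-to-ACD power law; upscale by stratification and by random forest;
#' fit and propagate the error model; validate both national maps against
#' LiDAR-scale truth by ecoregion. Artifacts are written under
#' `config$out_dir`; a manifest records every artifact with its MD5
#' checksum, so identical config + seed reproduces identical checksums for
#' deterministic outputs.
#'
#' @param config a `run_config` (or path to a YAML file).
#' @param verbose log stage progress via `message()` (default `TRUE`).
#' @return A `pipeline_run`: list with `manifest` (tibble: stage, artifact,
#'   path, md5, elapsed_s), `results` (in-memory stage outputs) and
#'   `config`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  known <- c("simulate", "inventory", "calibrate", "stratify", "ensemble",
             "errors", "validate")
  stages <- intersect(known, config$stages)  # canonical order
  res <- list()
  manifest <- tibble::tibble(stage = character(), artifact = character(),
                             path = character(), md5 = character(),
                             elapsed_s = numeric())
  add <- function(stage, paths_tbl, elapsed) {
    manifest <<- dplyr::bind_rows(
      manifest,
      dplyr::mutate(paths_tbl, stage = stage,
                    md5 = unname(tools::md5sum(path)),
                    elapsed_s = elapsed, .before = 1)[
                      , c("stage", "artifact", "path", "md5", "elapsed_s")])
  }
  need <- function(what, stage) {
    if (is.null(res[[what]]))
      stop(sprintf("stage '%s' needs '%s' output; enable that stage first",
                   stage, what), call. = FALSE)
    res[[what]]
  }
  run_stage <- function(stage, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    elapsed <- proc.time()[["elapsed"]] - t0
    add(stage, out$paths, elapsed)
    log_stage(stage, sprintf("done in %.1fs", elapsed), verbose)
    out$value
  }

  if ("simulate" %in% stages) {
    res$bundle <- run_stage("simulate", function() {
      cfg <- config$landscape
      cfg$seed <- stage_seed(config, "simulate")
      bundle <- generate_landscape(cfg)
      bundle$transect_mask <- sample_transects(bundle, config$spacing,
                                               config$swath)
      d <- file.path(config$out_dir, "landscape")
      list(value = bundle, paths = write_landscape(bundle, d))
    })
  }

  if ("inventory" %in% stages) {
    res$plots <- run_stage("inventory", function() {
      bundle <- need("bundle", "inventory")
      plots <- generate_plot_inventories(bundle, config$n_plots,
                                         seed = stage_seed(config, "inventory"))
      plots <- plot_acd(plots, hd = generating_hd_model(),
                        table = synthetic_wood_density_table())
      d <- file.path(config$out_dir, "plots")
      paths <- write_plot_inventories(plots, d)
      acd_path <- file.path(d, "plot_acd.csv")
      utils::write.csv(
        dplyr::select(plots, "plot_id", "area_ha", "n_stems", "agb_mg", "acd"),
        acd_path, row.names = FALSE)
      paths <- dplyr::bind_rows(paths,
                                tibble::tibble(artifact = "plot_acd",
                                               path = acd_path))
      list(value = plots, paths = paths)
    })
  }

  if ("calibrate" %in% stages) {
    res$fit <- run_stage("calibrate", function() {
      bundle <- need("bundle", "calibrate")
      plots <- need("plots", "calibrate")
      tch <- purrr::map_dbl(plots$footprint,
                            ~ as.numeric(plot_tch(bundle$chm, .x)))
      # treeless plots carry no height signal for a power law through the
      # origin; drop them from the calibration pairs
      keep <- tch > 0
      fit <- fit_power_law_ml(tch[keep], plots$acd[keep])
      p <- file.path(config$out_dir, "power_law_model.json")
      jsonlite::write_json(
        list(a = fit$a, b = fit$b, sigma0 = fit$sigma0, k = fit$k,
             report = as.list(fit$report), seed = config$seed),
        p, auto_unbox = TRUE, digits = NA)
      list(value = fit, paths = tibble::tibble(artifact = "power_law_model",
                                               path = p))
    })
  }

  # LiDAR-scale ACD for upscaling: power law applied to 1-ha mean TCH over
  # the transect cells
  lidar_acd_map <- function() {
    bundle <- res$bundle
    tch_ha <- aggregate_to_hectare(bundle$chm, bundle$config$fine_factor)
    predict_acd(res$fit, tch_ha)
  }

  if ("stratify" %in% stages) {
    res$strat <- run_stage("stratify", function() {
      bundle <- need("bundle", "stratify"); need("fit", "stratify")
      lidar_acd <- lidar_acd_map()
      strata <- build_strata(bundle$covariates)
      sm <- stratified_acd_map(strata, lidar_acd, bundle$transect_mask,
                               bundle$covariates$pv)
      d <- config$out_dir
      p1 <- file.path(d, "acd_stratified.asc")
      write_ascii_grid(sm$acd_map, p1)
      p2 <- file.path(d, "strata_table.csv")
      utils::write.csv(sm$strata_table, p2, row.names = FALSE)
      list(value = c(sm, list(lidar_acd = lidar_acd)),
           paths = tibble::tibble(artifact = c("acd_stratified", "strata_table"),
                                  path = c(p1, p2)))
    })
  }

  if ("ensemble" %in% stages) {
    res$ens <- run_stage("ensemble", function() {
      bundle <- need("bundle", "ensemble"); need("fit", "ensemble")
      lidar_acd <- lidar_acd_map()
      model <- train_ensemble(bundle$covariates, lidar_acd,
                              bundle$transect_mask,
                              stride = config$stride,
                              n_trees = config$n_trees,
                              seed = stage_seed(config, "ensemble"))
      pred <- predict_ensemble(model, bundle$covariates,
                               lidar_acd = lidar_acd,
                               lidar_mask = bundle$transect_mask,
                               overwrite_lidar = config$overwrite_lidar)
      p <- file.path(config$out_dir, "acd_ensemble.asc")
      write_ascii_grid(pred, p)
      list(value = list(model = model, acd_map = pred, lidar_acd = lidar_acd),
           paths = tibble::tibble(artifact = "acd_ensemble", path = p))
    })
  }

  if ("errors" %in% stages) {
    res$err <- run_stage("errors", function() {
      bundle <- need("bundle", "errors"); ens <- need("ens", "errors")
      mask <- bundle$transect_mask$values > 0
      em <- fit_rmse_polynomial(ens$acd_map$values[mask],
                                ens$lidar_acd$values[mask])
      err_map <- propagate_error_map(ens$acd_map, bundle$transect_mask, em)
      p1 <- file.path(config$out_dir, "acd_error.asc")
      write_ascii_grid(err_map, p1)
      p2 <- file.path(config$out_dir, "error_model.json")
      jsonlite::write_json(list(rmse_poly = em$rmse_poly,
                                bin_width = em$bin_width,
                                seed = config$seed),
                           p2, auto_unbox = TRUE, digits = NA)
      list(value = list(model = em, error_map = err_map),
           paths = tibble::tibble(artifact = c("acd_error", "error_model"),
                                  path = c(p1, p2)))
    })
  }

  if ("validate" %in% stages) {
    res$validation <- run_stage("validate", function() {
      bundle <- need("bundle", "validate")
      ens <- need("ens", "validate"); strat <- need("strat", "validate")
      truth <- bundle$true_acd
      rep_ens <- ecoregion_bias_report(ens$acd_map, truth,
                                       bundle$validation_regions,
                                       min_cells = 10)
      rep_str <- ecoregion_bias_report(strat$acd_map, truth,
                                       bundle$validation_regions,
                                       min_cells = 10)
      both <- dplyr::bind_rows(
        dplyr::mutate(rep_ens, method = "ensemble", .before = 1),
        dplyr::mutate(rep_str, method = "stratification", .before = 1))
      p <- file.path(config$out_dir, "ecoregion_bias.csv")
      utils::write.csv(both, p, row.names = FALSE)
      pj <- file.path(config$out_dir, "ecoregion_bias.json")
      jsonlite::write_json(both, pj, dataframe = "rows", digits = NA)
      list(value = both,
           paths = tibble::tibble(artifact = c("ecoregion_bias_csv",
                                               "ecoregion_bias_json"),
                                  path = c(p, pj)))
    })
  }

  manifest_path <- file.path(config$out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  structure(list(manifest = manifest, results = res, config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d stages, %d artifacts, out: %s\n",
              length(unique(x$manifest$stage)), nrow(x$manifest),
              x$config$out_dir))
  print(x$manifest, n = Inf)
  invisible(x)
}
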