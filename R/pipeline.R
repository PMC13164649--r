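PIPELINE_KEYS <- c(
  "species", "out_dir", "synthetic", "occurrences_csv", "raster_dir",
  "landcover_asc", "landcover_mapping_csv", "vif_threshold", "pa_ratio",
  "pa_sets", "buffer_km", "test_fraction", "n_reps", "schemes", "block_km",
  "k", "run_spatial_cv", "spatial_cv_family", "n_null", "run_null",
  "null_family", "p10_pct", "core_cut", "families", "ensemble_set",
  "n_perm", "seed", "verbose")

SYNTHETIC_KEYS <- c(
  "n_rows", "n_cols", "origin_lon", "origin_lat", "cell_size", "layers",
  "corr_range_cells", "ocean_fraction", "niche", "n_presences",
  "landcover_fraction", "landcover_cluster")

#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full per-species run.
#' Unknown keys are rejected; every tunable has the conventional default of
#' the workflow (VIF threshold 5, 10:1 background ratio, 10 background
#' sets, 1 km presence buffer, 30% test fraction, 10 replicates, 200 km
#' blocks with k = 5, 99 null replicates, 10th-percentile presence
#' threshold, 0.40 core cut, all four families).
#'
#' Inputs are either synthetic (a `synthetic` block: grid size, layer
#' names, correlation range, a virtual-species `niche`, presence count,
#' land-cover fraction) or files (`occurrences_csv`, `raster_dir` of .asc
#' layers, `landcover_asc` + `landcover_mapping_csv`).
#'
#' @param ... Configuration keys; see Details in the package vignette.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  unknown <- setdiff(names(user), PIPELINE_KEYS)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  cfg <- list(
    species = "virtual species", out_dir = tempfile("sdm_run_"),
    synthetic = NULL, occurrences_csv = NULL, raster_dir = NULL,
    landcover_asc = NULL, landcover_mapping_csv = NULL,
    vif_threshold = 5, pa_ratio = 10, pa_sets = 10, buffer_km = 1,
    test_fraction = 0.30, n_reps = 10, schemes = c("subsample", "bootstrap"),
    block_km = 200, k = 5L, run_spatial_cv = TRUE,
    spatial_cv_family = "randomized_tree_ensemble",
    n_null = 99L, run_null = TRUE, null_family = "linear_logistic",
    p10_pct = 10, core_cut = 0.40,
    families = MODEL_FAMILIES, ensemble_set = 1L, n_perm = 10L,
    seed = 1L, verbose = TRUE)
  cfg[names(user)] <- user
  stopifnot(cfg$vif_threshold > 1, cfg$pa_ratio >= 1, cfg$pa_sets >= 1,
            cfg$buffer_km >= 0, cfg$test_fraction > 0, cfg$test_fraction < 1,
            cfg$n_reps >= 1, cfg$block_km > 0, cfg$k >= 2,
            cfg$n_null >= 19, cfg$p10_pct >= 0, cfg$p10_pct <= 100,
            cfg$core_cut > 0, cfg$core_cut < 1,
            cfg$ensemble_set >= 1, cfg$n_perm >= 1)
  if (!all(cfg$schemes %in% c("subsample", "bootstrap")))
    stop("schemes must be drawn from subsample, bootstrap")
  cfg$families <- unname(vapply(cfg$families, canonical_family, ""))
  cfg$spatial_cv_family <- canonical_family(cfg$spatial_cv_family)
  cfg$null_family <- canonical_family(cfg$null_family)
  if (cfg$ensemble_set > cfg$pa_sets) stop("ensemble_set exceeds pa_sets")
  if (is.null(cfg$synthetic) && is.null(cfg$occurrences_csv))
    stop("provide either a `synthetic` block or file inputs")
  if (!is.null(cfg$synthetic)) {
    unknown <- setdiff(names(cfg$synthetic), SYNTHETIC_KEYS)
    if (length(unknown))
      stop(sprintf("unknown synthetic key(s): %s",
                   paste(unknown, collapse = ", ")))
    syn <- list(n_rows = 40L, n_cols = 40L, origin_lon = 100, origin_lat = 8,
                cell_size = 0.04, layers = c("vpd", "light", "sand", "silt",
                                             "clay", "elevation"),
                corr_range_cells = 5, ocean_fraction = 0,
                niche = list(vpd = list(optimum = 0.8, breadth = 0.2,
                                        weight = 1)),
                n_presences = 30L, landcover_fraction = 0.3,
                landcover_cluster = 4)
    syn[names(cfg$synthetic)] <- cfg$synthetic
    cfg$synthetic <- syn
  }
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(state, stage, msg) {
  line <- sprintf("[%s] %-18s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  if (state$verbose) message(line)
  cat(line, "\n", file = state$log_path, append = TRUE, sep = "")
}

build_inputs <- function(cfg, manifest) {
  if (!is.null(cfg$synthetic)) {
    syn <- cfg$synthetic
    spec <- grid_spec(syn$origin_lon, syn$origin_lat, syn$cell_size,
                      syn$n_rows, syn$n_cols)
    stack <- generate_environment(spec, syn$layers,
                                  corr_range_cells = syn$corr_range_cells,
                                  ocean_fraction = syn$ocean_fraction,
                                  seed = derive_seed(cfg$seed, "environment"))
    vs <- virtual_species(syn$niche)
    suit <- true_suitability(stack, vs)
    occ <- sample_presences(suit, syn$n_presences,
                            seed = derive_seed(cfg$seed, "presences"),
                            species = cfg$species)
    lc <- generate_landcover(spec, syn$landcover_fraction,
                             syn$landcover_cluster,
                             seed = derive_seed(cfg$seed, "landcover"),
                             mask = land_mask(stack))
    list(stack = stack, occ = occ, lc = lc, true_suit = suit)
  } else {
    files <- list.files(cfg$raster_dir, pattern = "\\.asc$", full.names = TRUE)
    if (!length(files)) stop(sprintf("no .asc layers in %s", cfg$raster_dir))
    layers <- list(); spec <- NULL
    for (f in files) {
      r <- read_raster_asc(f)
      if (is.null(spec)) spec <- r$spec else stop_if_not_conformal(spec, r$spec)
      layers[[sub("\\.asc$", "", basename(f))]] <- r$values
    }
    stack <- env_stack(spec, layers)
    occ <- read_occurrences(cfg$occurrences_csv, species = cfg$species)
    lc <- NULL
    if (!is.null(cfg$landcover_asc)) {
      r <- read_raster_asc(cfg$landcover_asc)
      mapping <- read_landcover_mapping(cfg$landcover_mapping_csv)
      codes <- r$values; storage.mode(codes) <- "integer"
      lc <- landcover_grid(r$spec, codes, mapping)
    }
    list(stack = stack, occ = occ, lc = lc, true_suit = NULL)
  }
}

#' Run the full per-species workflow
#'
#' Executes, in order: occurrence cleaning, extent filtering and
#' grid-resolution thinning; spatially constrained pseudo-absence
#' generation; predictor extraction and iterative VIF screening; replicated
#' fitting and evaluation of every family on every background set; spatial
#' block cross-validation; a null-model significance test; TSS-weighted
#' ensemble prediction; permutation variable importance; habitat
#' classification with latitude-corrected area accounting; and the
#' land-cover pressure overlay. All randomness derives from the single
#' master seed in the configuration, so a re-run with the same
#' configuration is bit-identical. Maps are written as .asc rasters, tables
#' as CSV, and the run manifest (configuration snapshot, per-stage seeds
#' and counts, key results) as JSON.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the manifest and the main in-memory
#'   objects (stack, tables, maps, summaries).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list(verbose = cfg$verbose,
                log_path = file.path(cfg$out_dir, "log.txt"))
  cat("", file = state$log_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rattanSDM")),
    species = cfg$species,
    config = cfg[setdiff(PIPELINE_KEYS, c("out_dir", "verbose"))],
    seeds = list(), counts = list(), results = list())

  pipeline_log(state, "inputs", "loading or generating inputs")
  inp <- build_inputs(cfg, manifest)
  stack <- inp$stack; lc <- inp$lc
  mask <- land_mask(stack)
  manifest$counts$n_land_cells <- sum(mask)

  pipeline_log(state, "occurrences", sprintf("%d raw record(s)", n_records(inp$occ)))
  occ <- clean_records(inp$occ)
  occ <- filter_extent(occ, stack)
  occ <- thin_to_grid(occ, stack$spec)
  manifest$counts$n_raw <- n_records(inp$occ)
  manifest$counts$n_clean_thinned <- n_records(occ)
  pipeline_log(state, "occurrences",
               sprintf("%d record(s) after cleaning/thinning", n_records(occ)))
  write_occurrences(occ, file.path(cfg$out_dir, "occurrences_clean.csv"))
  write_provenance(occ, file.path(cfg$out_dir, "provenance.json"))

  seed_bg <- derive_seed(cfg$seed, "background")
  manifest$seeds$background <- seed_bg
  pa <- sample_pseudo_absences(stack$spec, mask, occ, ratio = cfg$pa_ratio,
                               n_sets = cfg$pa_sets,
                               buffer_km = cfg$buffer_km, seed = seed_bg)
  manifest$counts$n_background_per_set <- nrow(pa[[1]]$points)
  manifest$counts$n_background_sets <- length(pa)
  pipeline_log(state, "background",
               sprintf("%d set(s) of %d pseudo-absences",
                       length(pa), nrow(pa[[1]]$points)))

  # VIF screening on the combined presence + background rows of the first
  # modeling table
  tab1 <- pb_table(stack, occ, pa[[1]])
  vif <- vif_filter(as.data.frame(tab1)[, pb_predictors(tab1), drop = FALSE],
                    threshold = cfg$vif_threshold)
  retained <- names(vif$table)
  manifest$results$vif_removed <- vif$removed
  manifest$results$vif_retained <- retained
  write_vif_report(vif, file.path(cfg$out_dir, "vif_report.csv"))
  pipeline_log(state, "vif", sprintf("retained %d of %d predictor(s)",
                                     length(retained),
                                     length(pb_predictors(tab1))))
  stack <- env_stack(stack$spec, stack$layers[retained])
  tables <- lapply(pa, function(s) pb_table(stack, occ, s))

  pipeline_log(state, "evaluate",
               sprintf("%d famil(ies) x %d set(s) x %d rep(s) x %d scheme(s)",
                       length(cfg$families), length(tables), cfg$n_reps,
                       length(cfg$schemes)))
  seed_eval <- derive_seed(cfg$seed, "evaluate")
  manifest$seeds$evaluate <- seed_eval
  records <- list()
  for (f in cfg$families) for (si in seq_along(tables))
    for (sch in cfg$schemes) {
      rec <- replicate_evaluate(f, tables[[si]], scheme = sch,
                                n_reps = cfg$n_reps,
                                test_fraction = cfg$test_fraction,
                                seed = derive_seed(seed_eval, f, si, sch))
      rec$set_id <- si
      records[[length(records) + 1L]] <- rec
    }
  records <- do.call(rbind, records)
  utils::write.csv(records, file.path(cfg$out_dir, "evaluation.csv"),
                   row.names = FALSE)

  weights <- tss_weights(records)
  manifest$results$weights <- as.list(unclass(weights))
  manifest$results$mean_tss <- as.list(stats::setNames(
    attr(weights, "mean_tss"), names(weights)))
  utils::write.csv(data.frame(family = names(weights),
                              mean_tss = attr(weights, "mean_tss"),
                              weight = as.numeric(weights)),
                   file.path(cfg$out_dir, "weights.csv"), row.names = FALSE)
  pipeline_log(state, "ensemble",
               paste(sprintf("%s=%.3f", names(weights), as.numeric(weights)),
                     collapse = " "))

  etab <- tables[[cfg$ensemble_set]]
  seed_fit <- derive_seed(cfg$seed, "final_fit")
  manifest$seeds$final_fit <- seed_fit
  models <- stats::setNames(lapply(cfg$families, function(f)
    sdm_fit(f, etab, seed = derive_seed(seed_fit, f))), cfg$families)
  maps <- lapply(models, predict_prob, newdata = stack)
  ens <- ensemble_predict(maps, weights)
  for (f in names(maps))
    write_raster_asc(maps[[f]]$values, stack$spec,
                     file.path(cfg$out_dir, sprintf("suitability_%s.asc", f)))
  write_raster_asc(ens$values, stack$spec,
                   file.path(cfg$out_dir, "suitability_ensemble.asc"))

  imp <- permutation_importance(models, weights, etab, n_perm = cfg$n_perm,
                                seed = derive_seed(cfg$seed, "importance"))
  utils::write.csv(imp$aggregated,
                   file.path(cfg$out_dir, "importance.csv"), row.names = FALSE)
  manifest$results$top_variable <- imp$aggregated$variable[1]

  if (cfg$run_spatial_cv) {
    pipeline_log(state, "spatial_cv", sprintf(
      "family %s, %g km blocks, k = %d", cfg$spatial_cv_family,
      cfg$block_km, cfg$k))
    folds <- assign_spatial_blocks(etab[, c("lon", "lat")],
                                   block_km = cfg$block_km, k = cfg$k,
                                   seed = derive_seed(cfg$seed, "blocks"),
                                   labels = etab$label)
    scv <- spatial_cv(cfg$spatial_cv_family, etab, folds,
                      seed = derive_seed(cfg$seed, "spatial_cv"))
    rand_auc <- mean(records$auc[records$family == cfg$spatial_cv_family &
                                   records$scheme == "subsample"])
    manifest$results$spatial_cv <- list(
      mean_auc = scv$mean_auc, random_split_auc = rand_auc,
      auc_drop = rand_auc - scv$mean_auc)
    utils::write.csv(scv$per_fold,
                     file.path(cfg$out_dir, "spatial_cv.csv"),
                     row.names = FALSE)
  }

  if (cfg$run_null) {
    pipeline_log(state, "null_model", sprintf("%d null replicate(s)", cfg$n_null))
    null_fit <- function(coords, seed) {
      nocc <- occurrence_set(cfg$species,
                             data.frame(lon = coords$lon, lat = coords$lat,
                                        event_year = NA_integer_,
                                        basis = "null", source = "synthetic"))
      npa <- sample_pseudo_absences(stack$spec, mask, nocc,
                                    ratio = cfg$pa_ratio, n_sets = 1,
                                    buffer_km = cfg$buffer_km,
                                    seed = derive_seed(seed, "bg"))
      ntab <- pb_table(stack, nocc, npa[[1]])
      parts <- with_seed(derive_seed(seed, "split"),
                         split_stratified(ntab$label, cfg$test_fraction))
      m <- sdm_fit(cfg$null_family, pb_rows(ntab, parts$train),
                   seed = derive_seed(seed, "fit"))
      auc(predict_prob(m, pb_rows(ntab, parts$test)),
          ntab$label[parts$test])
    }
    obs_auc <- local({
      parts <- with_seed(derive_seed(cfg$seed, "null_obs_split"),
                         split_stratified(etab$label, cfg$test_fraction))
      m <- sdm_fit(cfg$null_family, pb_rows(etab, parts$train),
                   seed = derive_seed(cfg$seed, "null_obs_fit"))
      auc(predict_prob(m, pb_rows(etab, parts$test)),
          etab$label[parts$test])
    })
    nd <- null_model_test(obs_auc, stack$spec, mask, n_records(occ), null_fit,
                          n_null = cfg$n_null,
                          seed = derive_seed(cfg$seed, "null"))
    manifest$results$null_test <- list(
      observed_auc = nd$observed, critical = nd$critical,
      significant = nd$significant)
    pipeline_log(state, "null_model", sprintf(
      "observed %.3f vs critical %.3f (%s)", nd$observed, nd$critical,
      if (nd$significant) "significant" else "not significant"))
  }

  suit_at_presence <- predict_prob_at(ens, occ$records$lon, occ$records$lat)
  p10 <- presence_threshold(suit_at_presence, cfg$p10_pct)
  p10c <- min(p10, cfg$core_cut)   # guard degenerate thresholds on tiny runs
  cls <- classify_habitat(ens, p10c, cfg$core_cut)
  areas <- class_area_summary(cls)
  manifest$results$p10 <- p10
  manifest$results$areas_km2 <- as.list(stats::setNames(areas$area_km2,
                                                        areas$class))
  write_raster_asc(cls$classes, stack$spec,
                   file.path(cfg$out_dir, "habitat_classes.asc"))
  utils::write.csv(areas, file.path(cfg$out_dir, "areas.csv"),
                   row.names = FALSE)
  pipeline_log(state, "habitat", sprintf(
    "p10 = %.3f; core %.0f km2, marginal %.0f km2", p10,
    areas$area_km2[areas$class == "core"],
    areas$area_km2[areas$class == "marginal"]))

  pressure <- NULL
  if (!is.null(lc)) {
    pressure <- pressure_summary(cls, lc)
    utils::write.csv(pressure, file.path(cfg$out_dir, "pressure.csv"),
                     row.names = FALSE)
    manifest$results$core_anthropogenic_pct <-
      pressure$anthropogenic[pressure$class == "core"]
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(state, "done", cfg$out_dir)
  invisible(list(manifest = manifest, stack = stack, occurrences = occ,
                 tables = tables, records = records, weights = weights,
                 models = models, maps = maps, ensemble = ens,
                 importance = imp, classes = cls, areas = areas,
                 pressure = pressure))
}

#' Sample a suitability map at point locations
#'
#' Containing-cell lookup of a suitability surface at lon/lat points (used
#' e.g. for the training-presence threshold).
#'
#' @param map A [suitability_map()].
#' @param lon,lat Coordinates (degrees).
#' @return Numeric vector (NA for points outside or in nodata cells).
#' @export
predict_prob_at <- function(map, lon, lat) {
  stopifnot(inherits(map, "suitability_map"))
  idx <- cell_index(map$spec, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(idx$row)
  out[ok] <- map$values[cbind(idx$row[ok], idx$col[ok])]
  out
}
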