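#' @title Pipeline orchestration
#' @description A single validated configuration drives the whole analysis:
#'   synthesize (or load) the environmental world, clean occurrences,
#'   sample pseudo-absences, select predictors, fit per-species ensembles,
#'   project scenarios and build community products. Every stage has its own
#'   seed derived from a master seed by a stable hash, so reruns with the
#'   same configuration are bit-identical for deterministic stages.
#' @name workflow
NULL

PIPELINE_STAGES <- c("synthesize", "qc", "pseudoabsence", "select", "fit",
                     "project", "community")

# stable, tiny string hash: stage seeds are reproducible across sessions and
# stay far below 2^31
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(master) %% 1000003L) * 1009L + h %% 100003L
}

config_defaults <- function() list(
  master_seed = 1,
  grid = list(n_rows = 60, n_cols = 80, x_min = -14, y_min = 4,
              resolution = 2.5 / 60),
  env = list(ocean_fraction = 0.15, layers = NULL),
  species = NULL,
  qc = list(baseline_year = 1969, tail_fraction = 0.10, min_records = 20,
            min_n = 60, blacklist = c("fossil", "unknown")),
  pseudoabsence = list(n = 1000, buffer_km = 500),
  selection = list(vif_threshold = 8, r_max = 0.7, priority = NULL),
  model = list(k = 4, algorithms = c("GLM", "GAM", "GBM", "RF"),
               weight_mode = "rescaled", hyper = list(),
               n_permutations = 5),
  scenarios = list(),
  landcover = list(fractions = c(forest = 0.35, shrubs = 0.2,
                                 grassland = 0.15, cropland = 0.15,
                                 sparse_vegetation = 0.05, urban = 0.1),
                   allowed = c("shrubs", "grassland", "cropland",
                               "sparse_vegetation")),
  community = list(min_richness = 25, focal_species = NULL,
                   overlap_layer = NULL)
)

#' Validate a pipeline configuration
#'
#' Fills defaults (1000 pseudo-absences within 500 km, VIF threshold 8,
#' |r| cutoff 0.7, fourfold CV, minimum 60 retained records, hotspot
#' richness 25, baseline year 1969) and rejects unknown keys anywhere in
#' the document.
#'
#' @param raw A named list (e.g. from `yaml::read_yaml()`) or a path to a
#'   YAML file.
#' @return The completed configuration, class `pipeline_config`.
#' @export
validate_config <- function(raw) {
  if (is.character(raw) && length(raw) == 1) raw <- yaml::read_yaml(raw)
  stopifnot(is.list(raw))
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (blk in c("qc", "pseudoabsence", "selection", "model", "landcover",
                "community", "grid", "env")) {
    bad <- setdiff(names(raw[[blk]]), names(defaults[[blk]]))
    if (length(bad))
      stop("unknown keys in '", blk, "': ", paste(bad, collapse = ", "))
  }
  cfg <- defaults
  for (nm in names(raw)) {
    # named parameter blocks merge key-by-key; list-valued sections
    # (species, scenarios, env$layers) replace wholesale
    if (nm %in% c("species", "scenarios")) {
      cfg[[nm]] <- raw[[nm]]
    } else if (nm == "env") {
      if (!is.null(raw$env$ocean_fraction))
        cfg$env$ocean_fraction <- raw$env$ocean_fraction
      if (!is.null(raw$env$layers)) cfg$env$layers <- raw$env$layers
    } else if (is.list(defaults[[nm]])) {
      cfg[[nm]] <- utils::modifyList(defaults[[nm]], raw[[nm]])
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  if (is.null(cfg$species) || !length(cfg$species))
    stop("configuration must define at least one species")
  if (is.null(cfg$env$layers) || !length(cfg$env$layers))
    stop("configuration must define environmental layers")
  labels <- vapply(cfg$scenarios, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("scenario labels must be unique")
  cfg$master_seed <- as.integer(cfg$master_seed)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' A small demonstration configuration
#'
#' Three virtual species with distinct niches on a six-layer stack
#' (four climatic, two edaphic), one future scenario with two GCM variants,
#' and a six-class land cover. Sized so the full pipeline runs in minutes on
#' one CPU.
#'
#' @param master_seed Master seed (default 42).
#' @return A validated `pipeline_config`.
#' @export
demo_config <- function(master_seed = 42) {
  validate_config(list(
    master_seed = master_seed,
    grid = list(n_rows = 60, n_cols = 80, x_min = -14, y_min = 4,
                resolution = 2.5 / 60),
    env = list(
      ocean_fraction = 0.15,
      layers = list(
        list(name = "BIO1", class = "climatic", mean = 26, sd = 1.2,
             smoothing = 4, gradient = 0.6),
        list(name = "BIO4", class = "climatic", mean = 120, sd = 40,
             smoothing = 4, gradient = -25),
        list(name = "BIO12", class = "climatic", mean = 1800, sd = 400,
             smoothing = 5, gradient = 0),
        list(name = "BIO18", class = "climatic", mean = 350, sd = 120,
             smoothing = 5, gradient = 0),
        list(name = "phh2o", class = "edaphic", mean = 58, sd = 6,
             smoothing = 3, gradient = 0),
        list(name = "nitrogen", class = "edaphic", mean = 180, sd = 50,
             smoothing = 3, gradient = 0)
      )
    ),
    species = list(
      list(id = "cocoa_like", prevalence = 0.25, n_clean = 350,
           contamination = list(n_ocean = 5, n_pre1969 = 8, n_duplicates = 20,
                                n_unknown_source = 6),
           response = list(BIO4 = list(optimum = 100, tolerance = 35),
                           BIO12 = list(optimum = 2000, tolerance = 450))),
      list(id = "shade_a", prevalence = 0.3, n_clean = 300,
           contamination = list(n_duplicates = 15),
           response = list(BIO1 = list(optimum = 26.5, tolerance = 1.2),
                           BIO18 = list(optimum = 420, tolerance = 140))),
      list(id = "shade_b", prevalence = 0.35, n_clean = 300,
           contamination = list(n_ocean = 3),
           response = list(BIO4 = list(optimum = 150, tolerance = 45),
                           phh2o = list(optimum = 55, tolerance = 7)))
    ),
    qc = list(min_n = 60),
    pseudoabsence = list(n = 1000, buffer_km = 500),
    model = list(hyper = list(gbm_nrounds = 300, gbm_eta = 0.05)),
    scenarios = list(
      list(label = "SSP585_2041-2060",
           gcms = list(
             list(label = "GCM1",
                  offset = list(BIO1 = 2.0, BIO4 = 25, BIO18 = -60)),
             list(label = "GCM2",
                  offset = list(BIO1 = 2.6, BIO4 = 35),
                  factor = list(BIO18 = 0.75))
           ))
    ),
    community = list(min_richness = 1, focal_species = "cocoa_like",
                     overlap_layer = "BIO4")
  ))
}

species_niches <- function(cfg) {
  lapply(cfg$species, function(s) {
    resp <- lapply(s$response, function(r)
      c(optimum = r$optimum, tolerance = r$tolerance))
    species_niche(s$id, resp,
                  if (is.null(s$prevalence)) 0.25 else s$prevalence)
  })
}

#' Run the pipeline
#'
#' Stages run in dependency order; prerequisites of requested stages are
#' computed in memory, but artifacts are written (and recorded in the
#' manifest) only for the requested stages. Every artifact row carries the
#' stage, path, MD5 checksum and the stage seed, giving full provenance.
#'
#' @param config A validated `pipeline_config` (see [validate_config()],
#'   [demo_config()]).
#' @param out_dir Output directory.
#' @param stages Subset of stages to produce (default: all).
#' @return The manifest data.frame, invisibly; columns `artifact`, `stage`,
#'   `path`, `md5`, `seed`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  last <- max(match(stages, PIPELINE_STAGES))
  active <- PIPELINE_STAGES[seq_len(last)]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(artifact = character(), stage = character(),
                         path = character(), md5 = character(),
                         seed = integer(), stringsAsFactors = FALSE)
  record <- function(stage, artifact, path, seed) {
    if (!(stage %in% stages)) return(invisible())
    manifest <<- rbind(manifest, data.frame(
      artifact = artifact, stage = stage, path = path,
      md5 = unname(tools::md5sum(path)), seed = seed,
      stringsAsFactors = FALSE))
  }
  msg <- function(stage, ...) message("[", stage, "] ", ...)

  ## synthesize ---------------------------------------------------------
  seed_syn <- derive_seed(config$master_seed, "synthesize")
  grid <- grid_spec(config$grid$n_rows, config$grid$n_cols,
                    config$grid$x_min, config$grid$y_min,
                    config$grid$resolution)
  env <- generate_env_stack(grid, config$env$layers, seed = seed_syn,
                            ocean_fraction = config$env$ocean_fraction)
  lc <- generate_landcover(grid, unlist(config$landcover$fractions),
                           seed = seed_syn + 1)
  niches <- species_niches(config)
  occ <- do.call(rbind, lapply(seq_along(niches), function(i) {
    s <- config$species[[i]]
    sample_occurrences(niches[[i]], env,
                       n_clean = s$n_clean,
                       contamination = if (is.null(s$contamination)) list()
                                       else s$contamination,
                       seed = seed_syn + 10 + i)
  }))
  msg("synthesize", length(niches), " species, ",
      nrow(occ), " occurrence records, ",
      sum(!env$nodata_mask), " land cells")
  if ("synthesize" %in% stages) {
    write_env_stack(env, file.path(out_dir, "env_current"))
    record("synthesize", "env_current", file.path(out_dir, "env_current", "stack.yml"), seed_syn)
    write_landcover(lc, file.path(out_dir, "landcover"))
    record("synthesize", "landcover", file.path(out_dir, "landcover", "landcover.asc"), seed_syn + 1)
    write_occurrences(occ, file.path(out_dir, "occurrences_raw.csv"))
    record("synthesize", "occurrences_raw", file.path(out_dir, "occurrences_raw.csv"), seed_syn)
  }
  if (last < 2) return(invisible(manifest))

  ## qc -----------------------------------------------------------------
  seed_qc <- derive_seed(config$master_seed, "qc")
  occ_qc <- run_qc(occ, env,
                   baseline_year = config$qc$baseline_year,
                   tail_fraction = config$qc$tail_fraction,
                   min_records = config$qc$min_records,
                   blacklist = config$qc$blacklist)
  kept_species <- apply_min_sample(occ_qc, config$qc$min_n)
  report <- qc_report(occ_qc)
  msg("qc", sum(qc_retained(occ_qc)), "/", nrow(occ_qc),
      " records retained; species kept: ",
      paste(kept_species, collapse = ", "))
  if ("qc" %in% stages) {
    write_occurrences(occ_qc, file.path(out_dir, "occurrences_qc.csv"))
    record("qc", "occurrences_qc", file.path(out_dir, "occurrences_qc.csv"), seed_qc)
    utils::write.csv(report, file.path(out_dir, "qc_report.csv"),
                     row.names = FALSE)
    record("qc", "qc_report", file.path(out_dir, "qc_report.csv"), seed_qc)
  }
  if (last < 3) return(invisible(manifest))
  if (!length(kept_species))
    stop("stage qc: no species passed the minimum-sample rule")

  ## pseudoabsence ------------------------------------------------------
  seed_pa <- derive_seed(config$master_seed, "pseudoabsence")
  presences <- lapply(kept_species, function(sp)
    occ_qc[occ_qc$species == sp & qc_retained(occ_qc), , drop = FALSE])
  names(presences) <- kept_species
  pa_sets <- lapply(seq_along(kept_species), function(i)
    sample_pseudoabsences(presences[[i]], env,
                          n = config$pseudoabsence$n,
                          buffer_km = config$pseudoabsence$buffer_km,
                          seed = seed_pa + i))
  names(pa_sets) <- kept_species
  msg("pseudoabsence", config$pseudoabsence$n, " points per species within ",
      config$pseudoabsence$buffer_km, " km")
  if ("pseudoabsence" %in% stages) {
    bg <- do.call(rbind, lapply(kept_species, function(sp)
      bind_background(presences[[sp]], pa_sets[[sp]])))
    utils::write.csv(bg, file.path(out_dir, "background_points.csv"),
                     row.names = FALSE)
    record("pseudoabsence", "background_points",
           file.path(out_dir, "background_points.csv"), seed_pa)
  }
  if (last < 4) return(invisible(manifest))

  ## select -------------------------------------------------------------
  seed_sel <- derive_seed(config$master_seed, "select")
  pooled <- do.call(rbind, lapply(kept_species, function(sp) {
    pts <- bind_background(presences[[sp]], pa_sets[[sp]])
    extract_env(env, pts$lon, pts$lat)
  }))
  pooled <- pooled[stats::complete.cases(pooled), , drop = FALSE]
  sel <- select_predictors(pooled,
                           vif_threshold = config$selection$vif_threshold,
                           r_max = config$selection$r_max,
                           priority = config$selection$priority)
  msg("select", "kept ", length(sel$kept), "/", ncol(pooled),
      " predictors: ", paste(sel$kept, collapse = ", "))
  if ("select" %in% stages) {
    sel_tab <- rbind(
      data.frame(name = sel$kept, stage = "kept", statistic = NA_real_,
                 stringsAsFactors = FALSE),
      sel$dropped)
    utils::write.csv(sel_tab, file.path(out_dir, "predictor_selection.csv"),
                     row.names = FALSE)
    record("select", "predictor_selection",
           file.path(out_dir, "predictor_selection.csv"), seed_sel)
  }
  if (last < 5) return(invisible(manifest))

  ## fit ----------------------------------------------------------------
  seed_fit <- derive_seed(config$master_seed, "fit")
  models <- list(); importances <- list(); metric_rows <- list()
  for (i in seq_along(kept_species)) {
    sp <- kept_species[i]
    tr <- build_training_set(presences[[sp]], pa_sets[[sp]], env,
                             predictors = sel$kept,
                             k = config$model$k, seed = seed_fit + i)
    m <- fit_ensemble(tr, algorithms = config$model$algorithms,
                      weight_mode = config$model$weight_mode,
                      seed = seed_fit + i, hyper = config$model$hyper)
    models[[sp]] <- m
    importances[[sp]] <- variable_importance(
      m, tr, env$variable_class,
      n_permutations = config$model$n_permutations, seed = seed_fit + i)
    cvm <- m$cv$metrics
    cvm$species <- sp
    metric_rows[[sp]] <- cvm
    msg("fit", sp, ": ensemble AUC ", round(m$auc, 3), ", TSS ",
        round(m$tss, 3), ", best ", m$best_algorithm)
  }
  if ("fit" %in% stages) {
    metrics <- do.call(rbind, metric_rows)
    utils::write.csv(metrics[, c("species", "algorithm", "fold", "auc",
                                 "tss", "threshold")],
                     file.path(out_dir, "cv_metrics.csv"), row.names = FALSE)
    record("fit", "cv_metrics", file.path(out_dir, "cv_metrics.csv"), seed_fit)
    imp <- do.call(rbind, lapply(importances, function(vi)
      data.frame(species = vi$species_id, algorithm = vi$algorithm,
                 variable = names(vi$importance),
                 importance = unname(vi$importance),
                 stringsAsFactors = FALSE)))
    utils::write.csv(imp, file.path(out_dir, "variable_importance.csv"),
                     row.names = FALSE)
    record("fit", "variable_importance",
           file.path(out_dir, "variable_importance.csv"), seed_fit)
  }
  if (last < 6) return(invisible(manifest))

  ## project ------------------------------------------------------------
  seed_prj <- derive_seed(config$master_seed, "project")
  current_maps <- lapply(models, predict_map, env = env)
  current_bin <- lapply(current_maps, function(m)
    binarize(m, models[[m$species_id]]$threshold))
  scenario_bin <- list(); scenario_maps <- list(); area_rows <- list()
  for (sc in config$scenarios) {
    shifted_envs <- lapply(sc$gcms, function(g)
      apply_scenario(env, scenario_shift(
        paste(sc$label, g$label, sep = "_"),
        offset = unlist(if (is.null(g$offset)) numeric() else g$offset),
        factor = unlist(if (is.null(g$factor)) numeric() else g$factor))))
    for (sp in kept_species) {
      per_gcm <- lapply(shifted_envs, function(e)
        predict_map(models[[sp]], e, scenario = sc$label))
      agg <- aggregate_gcms(per_gcm, scenario = sc$label)
      scenario_maps[[sc$label]][[sp]] <- agg
      bin <- binarize(agg, models[[sp]]$threshold)
      scenario_bin[[sc$label]][[sp]] <- bin
      area_rows[[paste(sc$label, sp)]] <- area_change(
        current_bin[[sp]], bin, landcover = lc,
        allowed = config$landcover$allowed)
    }
    msg("project", sc$label, ": ", length(sc$gcms), " GCMs x ",
        length(kept_species), " species")
  }
  if ("project" %in% stages) {
    for (sp in kept_species) {
      write_ascii_grid(current_maps[[sp]]$values, grid,
                       file.path(out_dir, paste0("suitability_", sp, "_current.asc")))
      record("project", paste0("suitability_", sp, "_current"),
             file.path(out_dir, paste0("suitability_", sp, "_current.asc")),
             seed_prj)
    }
    if (length(area_rows)) {
      utils::write.csv(area_change_table(area_rows),
                       file.path(out_dir, "area_change.csv"), row.names = FALSE)
      record("project", "area_change", file.path(out_dir, "area_change.csv"),
             seed_prj)
    }
  }
  if (last < 7) return(invisible(manifest))

  ## community ----------------------------------------------------------
  seed_com <- derive_seed(config$master_seed, "community")
  rich_now <- richness(unname(current_bin), scenario = "current")
  hs <- hotspots(rich_now, config$community$min_richness)
  roll <- importance_rollup(unname(importances), env$variable_class)
  if ("community" %in% stages) {
    write_ascii_grid(rich_now$values, grid,
                     file.path(out_dir, "richness_current.asc"))
    record("community", "richness_current",
           file.path(out_dir, "richness_current.asc"), seed_com)
    hs_num <- matrix(as.numeric(hs), grid$n_rows, grid$n_cols)
    write_ascii_grid(hs_num, grid, file.path(out_dir, "hotspots_current.asc"))
    record("community", "hotspots_current",
           file.path(out_dir, "hotspots_current.asc"), seed_com)
    utils::write.csv(roll$per_species,
                     file.path(out_dir, "importance_class_sums.csv"),
                     row.names = FALSE)
    record("community", "importance_class_sums",
           file.path(out_dir, "importance_class_sums.csv"), seed_com)
    focal <- config$community$focal_species
    if (!is.null(focal) && focal %in% kept_species) {
      layer_nm <- config$community$overlap_layer
      if (is.null(layer_nm)) layer_nm <- climatic_layers(env)[1]
      ov_cur <- overlap_summary(current_bin, current_maps[[focal]],
                                env$layers[[layer_nm]])
      if (length(scenario_bin)) {
        sc1 <- names(scenario_bin)[1]
        ov_fut <- overlap_summary(scenario_bin[[sc1]],
                                  scenario_maps[[sc1]][[focal]],
                                  env$layers[[layer_nm]])
        ov_cur <- overlap_shift(ov_cur, ov_fut)
      }
      utils::write.csv(ov_cur, file.path(out_dir, "overlap_summary.csv"),
                       row.names = FALSE)
      record("community", "overlap_summary",
             file.path(out_dir, "overlap_summary.csv"), seed_com)
    }
    for (sc_label in names(scenario_bin)) {
      rich_fut <- richness(unname(scenario_bin[[sc_label]]),
                           scenario = sc_label)
      write_ascii_grid(rich_fut$values, grid,
                       file.path(out_dir, paste0("richness_", sc_label, ".asc")))
      record("community", paste0("richness_", sc_label),
             file.path(out_dir, paste0("richness_", sc_label, ".asc")),
             seed_com)
    }
  }
  msg("community", "richness range ", min(rich_now$values, na.rm = TRUE),
      "-", max(rich_now$values, na.rm = TRUE), "; ",
      sum(hs, na.rm = TRUE), " hotspot cells")
  invisible(manifest)
}
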