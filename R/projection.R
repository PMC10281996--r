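#' @title Map projection, binarization and area accounting
#' @description Applies fitted ensembles across environmental stacks
#'   (current and scenario-shifted), averages over GCM variants, converts
#'   continuous suitability to binary suitable/unsuitable maps at the
#'   species' sensitivity+specificity-maximizing threshold, constrains them
#'   to land-cover classes available for agroforestry, and accounts suitable
#'   area (geodesic, cos-latitude weighted) and its change per scenario.
#' @name projection
NULL

#' Continuous suitability raster for one species and scenario
#'
#' @param species_id Species label.
#' @param scenario Scenario label (e.g. `"current"`, `"SSP585_2041-2060"`).
#' @param values Numeric matrix in \[0, 1\] (`NA` = nodata).
#' @param grid A [grid_spec()].
#' @return Object of class `suitability_map`.
#' @export
suitability_map <- function(species_id, scenario, values, grid) {
  stopifnot(is.matrix(values), inherits(grid, "grid_spec"),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    stop("suitability values must lie in [0, 1]")
  structure(list(species_id = species_id, scenario = scenario,
                 values = values, grid = grid),
            class = "suitability_map")
}

#' Binary suitable/unsuitable raster
#'
#' @param species_id,scenario Labels.
#' @param values Logical matrix (`NA` = nodata).
#' @param grid A [grid_spec()].
#' @param threshold The suitability cut that produced it.
#' @return Object of class `binary_map`.
#' @export
binary_map <- function(species_id, scenario, values, grid, threshold) {
  stopifnot(is.matrix(values), is.logical(values), inherits(grid, "grid_spec"),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  structure(list(species_id = species_id, scenario = scenario,
                 values = values, grid = grid, threshold = threshold),
            class = "binary_map")
}

#' Project an ensemble over an environmental stack
#'
#' Scores every land cell with the ensemble; nodata cells stay nodata.
#'
#' @param model An `ensemble_model`.
#' @param env An [env_stack()] containing all the model's predictors.
#' @param scenario Scenario label stored on the map (default `"current"`).
#' @return A [suitability_map()].
#' @export
predict_map <- function(model, env, scenario = "current") {
  stopifnot(inherits(model, "ensemble_model"), inherits(env, "env_stack"))
  miss <- setdiff(model$predictors, layer_names(env))
  if (length(miss))
    stop("stack is missing model predictors: ", paste(miss, collapse = ", "))
  cells <- land_cells(env)
  newdata <- as.data.frame(lapply(env$layers[model$predictors],
                                  function(m) m[cells]))
  names(newdata) <- model$predictors
  vals <- matrix(NA_real_, env$grid$n_rows, env$grid$n_cols)
  vals[cells] <- predict(model, newdata)
  suitability_map(model$species_id, scenario, vals, env$grid)
}

#' Average suitability maps across GCMs
#'
#' Future climate comes from several global climate models per SSP and
#' period; their per-cell arithmetic mean is the consensus projection.
#'
#' @param maps List of [suitability_map()]s on one shared grid.
#' @param scenario Label for the aggregate (default: first map's label).
#' @return A [suitability_map()].
#' @export
aggregate_gcms <- function(maps, scenario = NULL) {
  stopifnot(length(maps) >= 1)
  g <- maps[[1]]$grid
  for (m in maps)
    if (!same_grid(g, m$grid)) stop("maps must share one grid")
  avg <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  suitability_map(maps[[1]]$species_id,
                  if (is.null(scenario)) maps[[1]]$scenario else scenario,
                  avg, g)
}

#' Binarize a suitability map
#'
#' A cell is suitable iff its suitability is at or above the threshold
#' (typically the species' ensemble threshold, fit once on current
#' conditions and reused for futures).
#'
#' @param map A [suitability_map()].
#' @param threshold Threshold in (0, 1).
#' @return A [binary_map()].
#' @export
binarize <- function(map, threshold) {
  stopifnot(inherits(map, "suitability_map"),
            threshold > 0, threshold < 1)
  binary_map(map$species_id, map$scenario, map$values >= threshold,
             map$grid, threshold)
}

#' Constrain a binary map to allowed land-cover classes
#'
#' Suitable habitat only counts where it can actually host agroforestry
#' without deforestation (e.g. shrubs, grassland, cropland, sparse
#' vegetation). Class codes absent from the land-cover legend trigger a
#' warning and are treated as not allowed.
#'
#' @param binary A [binary_map()].
#' @param landcover A `landcover_raster` on the same grid.
#' @param allowed Allowed class names (or integer codes).
#' @return A [binary_map()] (same threshold) true only on suitable cells of
#'   allowed classes.
#' @export
mask_landcover <- function(binary, landcover, allowed) {
  stopifnot(inherits(binary, "binary_map"), inherits(landcover, "landcover_raster"))
  if (!same_grid(binary$grid, landcover$grid))
    stop("binary map and land cover must share one grid")
  if (is.character(allowed)) {
    unknown <- setdiff(allowed, names(landcover$classes))
    if (length(unknown))
      warning("unknown land-cover classes ignored: ",
              paste(unknown, collapse = ", "))
    codes <- unname(landcover$classes[intersect(allowed, names(landcover$classes))])
  } else {
    unknown <- setdiff(allowed, landcover$classes)
    if (length(unknown))
      warning("unknown land-cover codes ignored: ",
              paste(unknown, collapse = ", "))
    codes <- intersect(allowed, landcover$classes)
  }
  ok <- matrix(landcover$values %in% codes,
               binary$grid$n_rows, binary$grid$n_cols)
  binary_map(binary$species_id, binary$scenario,
             binary$values & ok, binary$grid, binary$threshold)
}

# Geodesic area (km^2) of the TRUE cells of a logical matrix.
suitable_area_km2 <- function(values, grid, mode = "geodesic") {
  row_area <- if (mode == "geodesic") cell_area_km2(grid)
              else rep(1, grid$n_rows)
  v <- values
  v[is.na(v)] <- FALSE
  sum(rowSums(v) * row_area)
}

#' Suitable-area change between two binary maps
#'
#' Areas are sums of geodesic cell areas (cos-latitude weighted; `mode =
#' "count"` switches to raw cell counts). Besides the summary, a
#' gain/loss/stable category raster is attached for mapping shifts.
#'
#' @param current,future [binary_map()]s on one shared grid.
#' @param landcover Optional `landcover_raster` for the constrained
#'   accounting.
#' @param allowed Allowed land-cover classes (with `landcover`).
#' @param mode `"geodesic"` (default) or `"count"`.
#' @return A list of class `area_change_summary`: species/scenario labels,
#'   `current_km2`, `future_km2`, `pct_of_study_area_current`,
#'   `pct_change`, the same four under the land-cover mask (`NA` when no
#'   land cover is given), and `change` — an integer raster coded 0 outside,
#'   1 loss, 2 stable, 3 gain.
#' @export
area_change <- function(current, future, landcover = NULL, allowed = NULL,
                        mode = c("geodesic", "count")) {
  stopifnot(inherits(current, "binary_map"), inherits(future, "binary_map"))
  mode <- match.arg(mode)
  if (!same_grid(current$grid, future$grid))
    stop("current and future maps must share one grid")
  grid <- current$grid
  study_area <- suitable_area_km2(!is.na(current$values), grid, mode)

  account <- function(cur, fut) {
    a_cur <- suitable_area_km2(cur$values, grid, mode)
    a_fut <- suitable_area_km2(fut$values, grid, mode)
    list(current = a_cur, future = a_fut,
         pct_of_study_area = 100 * a_cur / study_area,
         pct_change = if (a_cur > 0) 100 * (a_fut - a_cur) / a_cur
                      else NA_real_)
  }
  full <- account(current, future)
  masked <- list(current = NA_real_, future = NA_real_,
                 pct_of_study_area = NA_real_, pct_change = NA_real_)
  if (!is.null(landcover)) {
    masked <- account(mask_landcover(current, landcover, allowed),
                      mask_landcover(future, landcover, allowed))
  }
  cur <- current$values; fut <- future$values
  change <- matrix(0L, grid$n_rows, grid$n_cols)
  change[cur & !fut] <- 1L   # loss
  change[cur & fut] <- 2L    # stable
  change[!cur & fut] <- 3L   # gain
  change[is.na(cur) | is.na(fut)] <- NA_integer_
  structure(list(
    species_id = current$species_id,
    scenario_current = current$scenario, scenario_future = future$scenario,
    current_km2 = full$current, future_km2 = full$future,
    pct_of_study_area_current = full$pct_of_study_area,
    pct_change = full$pct_change,
    masked_current_km2 = masked$current, masked_future_km2 = masked$future,
    masked_pct_of_study_area_current = masked$pct_of_study_area,
    masked_pct_change = masked$pct_change,
    change = change, mode = mode
  ), class = "area_change_summary")
}

#' @export
print.area_change_summary <- function(x, ...) {
  cat(sprintf("area_change %s: %s -> %s\n", x$species_id,
              x$scenario_current, x$scenario_future))
  cat(sprintf(" suitable: %.0f -> %.0f km^2 (%.1f%% of study area; change %+.1f%%)\n",
              x$current_km2, x$future_km2, x$pct_of_study_area_current,
              x$pct_change))
  if (!is.na(x$masked_current_km2))
    cat(sprintf(" land-cover constrained: %.0f -> %.0f km^2 (change %+.1f%%)\n",
                x$masked_current_km2, x$masked_future_km2, x$masked_pct_change))
  invisible(x)
}

#' Flatten area-change summaries to a data.frame
#'
#' @param summaries List of `area_change_summary` objects.
#' @return A data.frame, one row per summary.
#' @export
area_change_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s)
    data.frame(species = s$species_id, current = s$scenario_current,
               future = s$scenario_future, current_km2 = s$current_km2,
               future_km2 = s$future_km2,
               pct_of_study_area_current = s$pct_of_study_area_current,
               pct_change = s$pct_change,
               masked_current_km2 = s$masked_current_km2,
               masked_future_km2 = s$masked_future_km2,
               masked_pct_change = s$masked_pct_change,
               stringsAsFactors = FALSE)))
}
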