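#' @title Community-level products: richness, hotspots, cocoa overlap
#' @description Stacks per-species binary maps into species-richness maps,
#'   delineates richness hotspots (strictly more than `min_richness` species
#'   per cell), summarizes each shade species' overlap with the focal crop's
#'   suitability and with a chosen environmental gradient inside the
#'   species' suitable area, and rolls per-species variable importances up
#'   into climatic vs edaphic class sums.
#' @name community_analysis
NULL

#' Species richness by stacking binary maps
#'
#' @param binaries List of [binary_map()]s on one shared grid.
#' @param scenario Label for the richness map (default: first map's label).
#' @return A list of class `richness_map`: integer matrix `values` (cellwise
#'   count of species with suitable habitat), `grid`, `scenario`, `species`.
#' @export
richness <- function(binaries, scenario = NULL) {
  stopifnot(length(binaries) >= 1)
  g <- binaries[[1]]$grid
  for (b in binaries)
    if (!same_grid(g, b$grid)) stop("binary maps must share one grid")
  acc <- Reduce(`+`, lapply(binaries, function(b) {
    v <- b$values
    storage.mode(v) <- "integer"
    v
  }))
  structure(list(values = acc, grid = g,
                 scenario = if (is.null(scenario)) binaries[[1]]$scenario
                            else scenario,
                 species = vapply(binaries, `[[`, "", "species_id")),
            class = "richness_map")
}

#' Richness hotspots
#'
#' A cell is a hotspot iff strictly more than `min_richness` species find it
#' suitable.
#'
#' @param rich A [richness()] map.
#' @param min_richness Strict lower bound (default 25 species).
#' @return Logical matrix (`NA` where richness is `NA`).
#' @export
hotspots <- function(rich, min_richness = 25) {
  stopifnot(inherits(rich, "richness_map"), min_richness >= 0)
  rich$values > min_richness
}

#' Per-species overlap with the focal crop and an environmental gradient
#'
#' For each species, the mean focal-crop (e.g. cocoa) suitability and the
#' mean of a chosen environmental layer are computed over the cells where
#' the species is suitable. Species with empty suitable area get `NA` means
#' and are flagged.
#'
#' @param binaries Named list of [binary_map()]s (one per species).
#' @param focal A [suitability_map()] of the focal crop, same grid.
#' @param env_layer Numeric matrix of the environmental gradient, same grid.
#' @return A data.frame: `species`, `scenario`, `n_suitable_cells`,
#'   `mean_focal_suitability`, `mean_env_layer`, `empty` (logical).
#' @export
overlap_summary <- function(binaries, focal, env_layer) {
  stopifnot(inherits(focal, "suitability_map"), is.matrix(env_layer))
  g <- focal$grid
  stopifnot(nrow(env_layer) == g$n_rows, ncol(env_layer) == g$n_cols)
  rows <- lapply(binaries, function(b) {
    if (!same_grid(g, b$grid)) stop("grids must match")
    cells <- which(b$values)
    empty <- length(cells) == 0
    data.frame(
      species = b$species_id, scenario = b$scenario,
      n_suitable_cells = length(cells),
      mean_focal_suitability = if (empty) NA_real_
                               else mean(focal$values[cells], na.rm = TRUE),
      mean_env_layer = if (empty) NA_real_
                       else mean(env_layer[cells], na.rm = TRUE),
      empty = empty, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Current-to-future shift of the overlap summary
#'
#' @param current,future [overlap_summary()] data.frames for the two
#'   scenarios (matched by species).
#' @return The current summary joined with future means and the shift
#'   (`d_focal`, `d_env`).
#' @export
overlap_shift <- function(current, future) {
  m <- match(current$species, future$species)
  current$future_focal_suitability <- future$mean_focal_suitability[m]
  current$future_env_layer <- future$mean_env_layer[m]
  current$d_focal <- current$future_focal_suitability - current$mean_focal_suitability
  current$d_env <- current$future_env_layer - current$mean_env_layer
  current
}

#' Roll variable importances up to climatic/edaphic class sums
#'
#' @param importances List of [variable_importance()] results.
#' @param variable_class Named map layer -> `"climatic"`/`"edaphic"`
#'   (checked against every importance's variables).
#' @return A list: `per_species` data.frame (species, climatic, edaphic) and
#'   `pooled` (mean and median of each class sum across species).
#' @export
importance_rollup <- function(importances, variable_class) {
  rows <- lapply(importances, function(vi) {
    stopifnot(inherits(vi, "variable_importance"))
    miss <- setdiff(names(vi$importance), names(variable_class))
    if (length(miss))
      stop("unknown variables in importance: ", paste(miss, collapse = ", "))
    cls <- variable_class[names(vi$importance)]
    data.frame(species = vi$species_id,
               climatic = sum(vi$importance[cls == "climatic"]),
               edaphic = sum(vi$importance[cls == "edaphic"]),
               stringsAsFactors = FALSE)
  })
  per_species <- do.call(rbind, rows)
  rownames(per_species) <- NULL
  list(per_species = per_species,
       pooled = data.frame(
         stat = c("mean", "median"),
         climatic = c(mean(per_species$climatic),
                      stats::median(per_species$climatic)),
         edaphic = c(mean(per_species$edaphic),
                     stats::median(per_species$edaphic))))
}
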