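#' Bundle named environmental layers on a shared grid
#'
#' An `env_stack` holds co-registered single-band rasters (matrices) on one
#' [grid_spec()], a shared nodata mask (TRUE = nodata, e.g. ocean), and a
#' class label per layer separating climatic predictors (the bioclimatic
#' BIO1-BIO19 family) from edaphic ones (soil properties such as phh2o, cec,
#' nitrogen, sand), mirroring the usual WorldClim + SoilGrids pairing.
#'
#' @param grid A [grid_spec()].
#' @param layers Named list of numeric matrices, all `n_rows` x `n_cols`.
#' @param variable_class Named character vector mapping every layer name to
#'   `"climatic"` or `"edaphic"`.
#' @param nodata_mask Logical matrix, TRUE where cells carry no data; applied
#'   to every layer.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(grid, layers, variable_class,
                      nodata_mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers), length(layers) >= 1)
  nms <- names(layers)
  if (is.null(nms) || anyDuplicated(nms) || any(nms == ""))
    stop("layers must have unique, non-empty names")
  for (nm in nms) {
    m <- layers[[nm]]
    if (!is.matrix(m) || nrow(m) != grid$n_rows || ncol(m) != grid$n_cols)
      stop("layer '", nm, "' does not match the grid dimensions")
  }
  if (is.null(nodata_mask))
    nodata_mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  stopifnot(is.logical(nodata_mask),
            nrow(nodata_mask) == grid$n_rows, ncol(nodata_mask) == grid$n_cols)
  vc <- variable_class[nms]
  if (anyNA(vc) || !all(vc %in% c("climatic", "edaphic")))
    stop("variable_class must label every layer as 'climatic' or 'edaphic'")
  names(vc) <- nms
  layers <- lapply(layers, function(m) { m[nodata_mask] <- NA; m })
  structure(list(grid = grid, layers = layers, variable_class = vc,
                 nodata_mask = nodata_mask),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layers (%d climatic, %d edaphic) on %d x %d grid, %.1f%% nodata\n",
              length(x$layers), sum(x$variable_class == "climatic"),
              sum(x$variable_class == "edaphic"),
              x$grid$n_rows, x$grid$n_cols, 100 * mean(x$nodata_mask)))
  cat(" layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

layer_names <- function(env) names(env$layers)

climatic_layers <- function(env)
  names(env$variable_class)[env$variable_class == "climatic"]

edaphic_layers <- function(env)
  names(env$variable_class)[env$variable_class == "edaphic"]

land_cells <- function(env) which(!env$nodata_mask)

#' Extract layer values at point locations
#'
#' Values are read from the cell containing each point; points outside the
#' grid or on nodata cells yield `NA`.
#'
#' @param env An [env_stack()].
#' @param lon,lat Point coordinates, decimal degrees.
#' @param layers Layer names to extract (default: all).
#' @return A data.frame, one column per layer, one row per point.
#' @export
extract_env <- function(env, lon, lat, layers = NULL) {
  stopifnot(inherits(env, "env_stack"))
  if (is.null(layers)) layers <- layer_names(env)
  missing_layers <- setdiff(layers, layer_names(env))
  if (length(missing_layers))
    stop("layers not in stack: ", paste(missing_layers, collapse = ", "))
  idx <- cell_index(env$grid, lon, lat)
  lin <- ifelse(is.na(idx$row), NA_integer_,
                (idx$col - 1L) * env$grid$n_rows + idx$row)
  out <- lapply(layers, function(nm) {
    v <- rep(NA_real_, length(lon))
    ok <- !is.na(lin)
    v[ok] <- env$layers[[nm]][lin[ok]]
    v
  })
  names(out) <- layers
  as.data.frame(out, optional = TRUE)
}

#' Write / read an environmental stack as ASCII grids plus a YAML sidecar
#'
#' Each layer goes to `<dir>/<name>.asc`; `<dir>/stack.yml` records layer
#' order and climatic/edaphic classes so a stack round-trips losslessly.
#'
#' @param env An [env_stack()].
#' @param dir Directory (created if needed).
#' @return `dir` invisibly (writer); an [env_stack()] (reader).
#' @export
write_env_stack <- function(env, dir) {
  stopifnot(inherits(env, "env_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in layer_names(env))
    write_ascii_grid(env$layers[[nm]], env$grid, file.path(dir, paste0(nm, ".asc")))
  yaml::write_yaml(list(layers = as.list(env$variable_class)),
                   file.path(dir, "stack.yml"))
  invisible(dir)
}

#' @rdname write_env_stack
#' @export
read_env_stack <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "stack.yml"))
  vc <- unlist(meta$layers)
  rasters <- lapply(names(vc), function(nm)
    read_ascii_grid(file.path(dir, paste0(nm, ".asc"))))
  layers <- lapply(rasters, `[[`, "values")
  names(layers) <- names(vc)
  mask <- Reduce(`|`, lapply(layers, is.na))
  env_stack(rasters[[1]]$grid, layers, vc, nodata_mask = mask)
}
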