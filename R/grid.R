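#' Define a regular longitude/latitude analysis grid
#'
#' The grid is north-up: row 1 is the northernmost row, column 1 the
#' westernmost column. Coordinates refer to cell centers and the extent is
#' half-open, `[x_min, x_max)` by `[y_min, y_max)`. The default resolution is
#' 2.5 arc-minutes (2.5/60 degrees), the resolution at which occurrence
#' records are thinned and models are projected.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param x_min,y_min Western and southern edge of the extent, decimal degrees
#'   (WGS84).
#' @param resolution Cell size in degrees (same in x and y).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(24, 36, x_min = -14, y_min = 4)
#' g$x_max - g$x_min  # 36 * 2.5/60 degrees
#' @export
grid_spec <- function(n_rows, n_cols, x_min = 0, y_min = 0,
                      resolution = 2.5 / 60) {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1)
  if (n_rows < 1 || n_cols < 1 || n_rows != round(n_rows) || n_cols != round(n_cols))
    stop("n_rows and n_cols must be positive integers")
  if (!is.finite(resolution) || resolution <= 0)
    stop("resolution must be positive")
  g <- structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    x_min = x_min, y_min = y_min,
    x_max = x_min + n_cols * resolution,
    y_max = y_min + n_rows * resolution,
    resolution = resolution
  ), class = "grid_spec")
  if (g$y_max > 90 + 1e-9 || g$y_min < -90 - 1e-9)
    stop("grid extends beyond valid latitudes")
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, %.6g deg, extent [%.4g, %.4g) x [%.4g, %.4g)\n",
              x$n_rows, x$n_cols, x$resolution,
              x$x_min, x$x_max, x$y_min, x$y_max))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$x_min - b$x_min) < tol && abs(a$y_min - b$y_min) < tol &&
    abs(a$resolution - b$resolution) < tol
}

#' Locate points on a grid
#'
#' Maps longitude/latitude pairs to (row, col) cell indices. Points outside
#' the half-open extent get `NA` indices.
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Numeric vectors of equal length.
#' @return A data.frame with columns `row` and `col` (integer, `NA` outside
#'   the extent).
#' @export
cell_index <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "grid_spec"), length(lon) == length(lat))
  col <- floor((lon - grid$x_min) / grid$resolution) + 1
  row <- floor((grid$y_max - lat) / grid$resolution) + 1
  bad <- !is.finite(lon) | !is.finite(lat) |
    col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Coordinates of cell centers
#'
#' @param grid A [grid_spec()].
#' @param row,col Integer vectors of equal length (1-based).
#' @return A data.frame with columns `lon` and `lat`.
#' @export
cell_center <- function(grid, row, col) {
  stopifnot(inherits(grid, "grid_spec"))
  data.frame(lon = grid$x_min + (col - 0.5) * grid$resolution,
             lat = grid$y_max - (row - 0.5) * grid$resolution)
}

#' Geodesic area of each grid row
#'
#' Cell area on the sphere depends on latitude: a cell spanning longitudes
#' `dlam` and latitudes `[phi_b, phi_t]` has area
#' `R^2 * dlam * (sin(phi_t) - sin(phi_b))` with `R = 6371` km. All cells in
#' one row share a latitude band, so areas are returned per row.
#'
#' @param grid A [grid_spec()].
#' @return Numeric vector of length `n_rows`: the area in km^2 of one cell in
#'   each row (row 1 = northernmost).
#' @export
cell_area_km2 <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  R <- 6371
  top <- grid$y_max - (seq_len(grid$n_rows) - 1) * grid$resolution
  bot <- top - grid$resolution
  dlam <- grid$resolution * pi / 180
  R^2 * dlam * (sin(top * pi / 180) - sin(bot * pi / 180))
}

#' Great-circle distance (haversine)
#'
#' Vectorized haversine distance on a sphere of radius 6371 km. Arguments
#' recycle as usual.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Write / read a raster as ESRI ASCII grid
#'
#' Plain-text single-band raster exchange format: a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of values, northernmost row first — matching this package's matrix
#' layout directly.
#'
#' @param values Numeric matrix (`n_rows` x `n_cols`), `NA` = nodata.
#' @param grid A [grid_spec()].
#' @param path Output file path.
#' @param nodata Sentinel written for `NA` cells.
#' @return `path`, invisibly (writer); a list with `values` (matrix) and
#'   `grid` (reader).
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  stopifnot(is.matrix(values), inherits(grid, "grid_spec"),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    paste("xllcorner", format(grid$x_min, digits = 15)),
    paste("yllcorner", format(grid$y_min, digits = 15)),
    paste("cellsize", format(grid$resolution, digits = 15)),
    paste("NODATA_value", nodata)
  ), con)
  v <- values
  v[is.na(v)] <- nodata
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1))
  val <- as.numeric(vapply(kv, `[`, "", 2))
  names(val) <- key
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == val[["nodata_value"]]] <- NA
  grid <- grid_spec(val[["nrows"]], val[["ncols"]],
                    x_min = val[["xllcorner"]], y_min = val[["yllcorner"]],
                    resolution = val[["cellsize"]])
  list(values = v, grid = grid)
}
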