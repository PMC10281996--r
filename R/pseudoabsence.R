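#' @title Pseudo-absence sampling
#' @description SDM calibration needs absence data, which are rarely
#'   available; instead background "pseudo-absence" points are drawn at
#'   random from the region accessible to the species: land cells within a
#'   great-circle buffer (default 500 km) of at least one presence, excluding
#'   cells that contain a presence. The sampling unit is the grid cell
#'   (without replacement, point at the cell center), matching the raster
#'   resolution at which models are fitted.
#' @name pseudoabsence
NULL

#' Cells eligible for pseudo-absence sampling
#'
#' A cell is eligible iff it is land, its center lies strictly within
#' `buffer_km` (haversine) of at least one presence, and no presence falls
#' in it.
#'
#' @param presences Data.frame with `lon` and `lat` of presence records.
#' @param env An [env_stack()].
#' @param buffer_km Buffer radius in km (default 500).
#' @return Logical matrix (grid-shaped), TRUE = eligible.
#' @export
eligible_cells <- function(presences, env, buffer_km = 500) {
  stopifnot(inherits(env, "env_stack"), nrow(presences) >= 1)
  grid <- env$grid
  elig <- matrix(FALSE, grid$n_rows, grid$n_cols)
  land <- land_cells(env)
  if (!length(land)) stop("no land cells in stack")
  rc <- arrayInd(land, c(grid$n_rows, grid$n_cols))
  ctr <- cell_center(grid, rc[, 1], rc[, 2])
  near <- rep(FALSE, length(land))
  for (i in seq_len(nrow(presences))) {
    d <- haversine_km(ctr$lon, ctr$lat, presences$lon[i], presences$lat[i])
    near <- near | (d < buffer_km)
    if (all(near)) break
  }
  elig[land[near]] <- TRUE
  pidx <- cell_index(grid, presences$lon, presences$lat)
  on <- !is.na(pidx$row)
  elig[cbind(pidx$row[on], pidx$col[on])] <- FALSE
  if (!any(elig)) stop("no eligible cells within ", buffer_km,
                       " km of the presences")
  elig
}

#' Draw pseudo-absence points
#'
#' Samples `n` distinct eligible cells uniformly at random (without
#' replacement) and places one point at each cell center. Deterministic
#' given the seed.
#'
#' @param presences Data.frame with `lon`, `lat` and optionally `species`.
#' @param env An [env_stack()].
#' @param n Number of pseudo-absences (default 1000).
#' @param buffer_km Buffer radius in km (default 500).
#' @param seed Integer seed.
#' @return A data.frame of class `pseudoabsence_set` with columns `species`,
#'   `lon`, `lat`; attributes `buffer_km`, `n`, `seed`.
#' @export
sample_pseudoabsences <- function(presences, env, n = 1000, buffer_km = 500,
                                  seed = 1) {
  elig <- eligible_cells(presences, env, buffer_km)
  cells <- which(elig)
  if (length(cells) < n)
    stop("only ", length(cells), " eligible cells for n = ", n,
         " pseudo-absences (shortfall ", n - length(cells), ")")
  pick <- with_seed(seed, sample(cells, n, replace = FALSE))
  rc <- arrayInd(pick, c(env$grid$n_rows, env$grid$n_cols))
  ctr <- cell_center(env$grid, rc[, 1], rc[, 2])
  sp <- if (!is.null(presences$species)) presences$species[1] else NA_character_
  out <- data.frame(species = sp, lon = ctr$lon, lat = ctr$lat,
                    stringsAsFactors = FALSE)
  structure(out, class = c("pseudoabsence_set", "data.frame"),
            buffer_km = buffer_km, n = n, seed = seed)
}

#' Combine presences and pseudo-absences into a labelled point table
#'
#' @param presences Data.frame with `species`, `lon`, `lat`.
#' @param pa A [sample_pseudoabsences()] result.
#' @return Data.frame `species, lon, lat, label` with label
#'   `"presence"`/`"pseudoabsence"`.
#' @export
bind_background <- function(presences, pa) {
  rbind(
    data.frame(species = presences$species, lon = presences$lon,
               lat = presences$lat, label = "presence",
               stringsAsFactors = FALSE),
    data.frame(species = pa$species, lon = pa$lon, lat = pa$lat,
               label = "pseudoabsence", stringsAsFactors = FALSE)
  )
}
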