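#' @title Synthetic worlds for pipeline validation
#' @description Generators for spatially autocorrelated environmental stacks,
#'   virtual species with known Gaussian niches, contaminated occurrence
#'   samples, shifted future scenarios and categorical land-cover rasters.
#'   Every generator is a pure function of its parameters and a seed, so
#'   downstream stages can be tested against known truth with no downloads.
#' @name synthetic
NULL

# Run code under a local RNG state so generators are seeded without
# clobbering the caller's random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Separable Gaussian kernel smoothing with edge renormalization; `scale` is
# the kernel sd in cells. Dense banded-operator form: fine for the grid sizes
# this package simulates.
smooth_field <- function(m, scale) {
  if (scale <= 0) return(m)
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-0.5 * (d / scale)^2)
    k[d > ceiling(3 * scale)] <- 0
    k / rowSums(k)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

lat_matrix <- function(grid) {
  matrix(cell_center(grid, seq_len(grid$n_rows), 1)$lat,
         grid$n_rows, grid$n_cols)
}

#' Generate a spatially autocorrelated environmental stack
#'
#' Each layer is an optional north-south linear gradient plus a Gaussian
#' random field (kernel-smoothed white noise), linearly rescaled so the
#' realized mean and standard deviation over land match the request exactly.
#' An optional contiguous "ocean" (nodata) region is carved from an
#' independent smoothed field so occurrence QC and pseudo-absence sampling
#' can be exercised.
#'
#' @param grid A [grid_spec()].
#' @param layer_specs List of per-layer specs: each a list with elements
#'   `name`, `class` ("climatic"/"edaphic"), `mean`, `sd`, and optionally
#'   `smoothing` (kernel sd in cells, default 3) and `gradient` (units per
#'   degree latitude, default 0).
#' @param seed Integer seed; the stack is a pure function of
#'   (grid, layer_specs, seed, ocean_fraction).
#' @param ocean_fraction Fraction of cells set to nodata (default 0).
#' @return An [env_stack()].
#' @examples
#' g <- grid_spec(30, 30, x_min = -10, y_min = 4)
#' env <- generate_env_stack(g, list(
#'   list(name = "BIO1", class = "climatic", mean = 26, sd = 1.5),
#'   list(name = "phh2o", class = "edaphic", mean = 60, sd = 8)
#' ), seed = 1, ocean_fraction = 0.15)
#' @export
generate_env_stack <- function(grid, layer_specs, seed, ocean_fraction = 0) {
  stopifnot(inherits(grid, "grid_spec"), length(layer_specs) >= 1)
  nms <- vapply(layer_specs, function(s) s$name, "")
  if (anyDuplicated(nms)) stop("duplicate layer name in layer_specs")
  if (ocean_fraction < 0 || ocean_fraction >= 1)
    stop("ocean_fraction must be in [0, 1)")
  with_seed(seed, {
    mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
    if (ocean_fraction > 0) {
      sea <- smooth_field(matrix(stats::rnorm(grid$n_rows * grid$n_cols),
                                 grid$n_rows, grid$n_cols), scale = 4)
      mask <- sea < stats::quantile(sea, ocean_fraction)
    }
    latm <- lat_matrix(grid)
    layers <- lapply(layer_specs, function(s) {
      smoothing <- if (is.null(s$smoothing)) 3 else s$smoothing
      gradient <- if (is.null(s$gradient)) 0 else s$gradient
      if (smoothing < 0) stop("smoothing-scale must be >= 0")
      noise <- smooth_field(matrix(stats::rnorm(grid$n_rows * grid$n_cols),
                                   grid$n_rows, grid$n_cols), smoothing)
      if (stats::sd(noise) > 0)
        noise <- (noise - mean(noise)) / stats::sd(noise)
      raw <- gradient * (latm - mean(latm)) + s$sd * noise
      land <- !mask
      s_raw <- stats::sd(raw[land])
      if (s$sd == 0 && gradient == 0) {
        out <- matrix(s$mean, grid$n_rows, grid$n_cols)
      } else if (s_raw == 0) {
        out <- matrix(s$mean, grid$n_rows, grid$n_cols)
      } else {
        out <- s$mean + (raw - mean(raw[land])) / s_raw * s$sd
      }
      out
    })
    names(layers) <- nms
    vc <- vapply(layer_specs, function(s) s$class, "")
    names(vc) <- nms
    env_stack(grid, layers, vc, nodata_mask = mask)
  })
}

#' Define a virtual species with a known niche
#'
#' The species' true habitat suitability is the product of independent
#' Gaussian responses, one per environmental layer: at a cell with value `x`
#' on a layer with optimum `mu` and tolerance `tau`, the layer contributes
#' `exp(-0.5 * ((x - mu)/tau)^2)`. Infinite tolerance means indifference to
#' that layer.
#'
#' @param species_id Species label.
#' @param response Named list, one entry per layer the species responds to,
#'   each `c(optimum = , tolerance = )`.
#' @param prevalence_target Target mean suitability over land, in (0, 1).
#' @return Object of class `species_niche`.
#' @export
species_niche <- function(species_id, response, prevalence_target = 0.25) {
  stopifnot(is.character(species_id), length(species_id) == 1,
            is.list(response), length(response) >= 1)
  if (!(prevalence_target > 0 && prevalence_target < 1))
    stop("prevalence_target must be in (0, 1)")
  tol <- vapply(response, function(r) r[["tolerance"]], 0)
  if (!any(is.finite(tol)))
    stop("at least one layer must have finite tolerance")
  structure(list(species_id = species_id, response = response,
                 prevalence_target = prevalence_target),
            class = "species_niche")
}

#' True habitat suitability of a virtual species
#'
#' Evaluates the product-Gaussian niche on an environmental stack, then
#' rescales multiplicatively (capped at 1) so the mean over land approximates
#' `prevalence_target`. Nodata propagates.
#'
#' @param truth A [species_niche()].
#' @param env An [env_stack()].
#' @return A [suitability_map()] with scenario label `"truth"`.
#' @export
true_suitability <- function(truth, env) {
  stopifnot(inherits(truth, "species_niche"), inherits(env, "env_stack"))
  miss <- setdiff(names(truth$response), layer_names(env))
  if (length(miss))
    stop("response layers missing from stack: ", paste(miss, collapse = ", "))
  raw <- matrix(1, env$grid$n_rows, env$grid$n_cols)
  for (nm in names(truth$response)) {
    r <- truth$response[[nm]]
    if (is.finite(r[["tolerance"]])) {
      z <- (env$layers[[nm]] - r[["optimum"]]) / r[["tolerance"]]
      raw <- raw * exp(-0.5 * z^2)
    }
  }
  raw[env$nodata_mask] <- NA
  m <- mean(raw[!env$nodata_mask])
  if (!is.finite(m) || m <= 0) stop("degenerate niche: zero suitability everywhere")
  suit <- pmin(raw * truth$prevalence_target / m, 1)
  suitability_map(truth$species_id, "truth", suit, env$grid)
}

#' Sample virtual occurrence records, optionally contaminated
#'
#' Clean records are drawn from land cells with probability proportional to
#' true suitability, given a collection year in `[year_range]` and a small
#' within-cell coordinate jitter (<= 0.4 cell) so sub-cell duplicates occur,
#' as in real herbarium data. Contaminated records of known classes are then
#' injected for QC testing: points in the ocean, pre-baseline collection
#' years, exact coordinate duplicates, climatically marginal locations, and
#' records from blacklisted sources. The hidden column `.truth` records each
#' row's class so filters can be audited.
#'
#' @param truth A [species_niche()].
#' @param env An [env_stack()].
#' @param n_clean Number of clean presence records (>= 1).
#' @param contamination List with any of `n_ocean`, `n_pre1969`,
#'   `n_duplicates`, `n_marginal`, `n_unknown_source` (all default 0).
#' @param seed Integer seed.
#' @param year_range Collection years for clean records (default 1969-2020).
#' @return A data.frame with columns `species`, `lon`, `lat`, `year`,
#'   `source` and `.truth`.
#' @export
sample_occurrences <- function(truth, env, n_clean,
                               contamination = list(), seed = 1,
                               year_range = c(1969, 2020)) {
  stopifnot(inherits(truth, "species_niche"), inherits(env, "env_stack"),
            n_clean >= 1)
  spec <- utils::modifyList(
    list(n_ocean = 0, n_pre1969 = 0, n_duplicates = 0, n_marginal = 0,
         n_unknown_source = 0),
    contamination)
  unknown <- setdiff(names(contamination),
                     c("n_ocean", "n_pre1969", "n_duplicates", "n_marginal",
                       "n_unknown_source"))
  if (length(unknown))
    stop("unknown contamination class: ", paste(unknown, collapse = ", "))
  suit <- true_suitability(truth, env)$values
  grid <- env$grid
  land <- land_cells(env)
  ocean <- which(env$nodata_mask)
  if (spec$n_ocean > length(ocean))
    stop("contamination exceeds grid capacity: only ", length(ocean),
         " ocean cells for n_ocean = ", spec$n_ocean)

  with_seed(seed, {
    draw <- function(cells, n, years, source, truth_label, jitter = TRUE) {
      if (n == 0) return(NULL)
      rc <- arrayInd(cells, c(grid$n_rows, grid$n_cols))
      ctr <- cell_center(grid, rc[, 1], rc[, 2])
      j <- if (jitter) grid$resolution * 0.4 else 0
      data.frame(
        species = truth$species_id,
        lon = ctr$lon + stats::runif(n, -j, j),
        lat = ctr$lat + stats::runif(n, -j, j),
        year = sample(seq(years[1], years[2]), n, replace = TRUE),
        source = source,
        .truth = truth_label,
        stringsAsFactors = FALSE
      )
    }
    p <- suit[land]
    if (all(p == 0)) stop("true suitability is zero on every land cell")
    clean_cells <- sample(land, n_clean, replace = TRUE, prob = p)
    out <- draw(clean_cells, n_clean, year_range, "field", "clean")

    if (spec$n_ocean > 0) {
      cells <- sample(ocean, spec$n_ocean,
                      replace = FALSE)
      out <- rbind(out, draw(cells, spec$n_ocean, year_range, "field", "ocean"))
    }
    if (spec$n_pre1969 > 0) {
      cells <- sample(land, spec$n_pre1969, replace = TRUE, prob = p)
      out <- rbind(out, draw(cells, spec$n_pre1969, c(1900, year_range[1] - 1),
                             "field", "pre1969"))
    }
    if (spec$n_duplicates > 0) {
      pick <- sample(n_clean, spec$n_duplicates, replace = TRUE)
      dup <- out[pick, , drop = FALSE]
      dup$.truth <- "duplicate"
      rownames(dup) <- NULL
      out <- rbind(out, dup)
    }
    if (spec$n_marginal > 0) {
      # most climatically extreme land cells on the first finite-tolerance layer
      lay <- names(truth$response)[which(
        vapply(truth$response, function(r) is.finite(r[["tolerance"]]), TRUE))[1]]
      v <- env$layers[[lay]][land]
      cells <- land[order(v, decreasing = TRUE)][seq_len(spec$n_marginal)]
      out <- rbind(out, draw(cells, spec$n_marginal, year_range, "field",
                             "marginal", jitter = FALSE))
    }
    if (spec$n_unknown_source > 0) {
      cells <- sample(land, spec$n_unknown_source, replace = TRUE, prob = p)
      bad <- draw(cells, spec$n_unknown_source, year_range, "field",
                  "unknown_source")
      bad$source <- sample(c("fossil", "unknown"), spec$n_unknown_source,
                           replace = TRUE)
      out <- rbind(out, bad)
    }
    rownames(out) <- NULL
    out
  })
}

#' Define a future-scenario shift for climatic layers
#'
#' A scenario is an affine perturbation per climatic layer:
#' `layer <- layer * factor + offset`. Edaphic layers are never shifted
#' (soil is held constant under future scenarios).
#'
#' @param label Scenario label, e.g. `"SSP585_2041-2060_GCM1"`.
#' @param offset,factor Named numeric vectors keyed by climatic layer name;
#'   layers not named are unchanged. All factors must be positive.
#' @return Object of class `scenario_shift`.
#' @export
scenario_shift <- function(label, offset = numeric(), factor = numeric()) {
  stopifnot(is.character(label), length(label) == 1)
  if (length(offset) && is.null(names(offset))) stop("offset must be named")
  if (length(factor) && is.null(names(factor))) stop("factor must be named")
  if (any(factor <= 0)) stop("scenario factors must be > 0")
  structure(list(label = label, offset = offset, factor = factor),
            class = "scenario_shift")
}

#' Apply a scenario shift to an environmental stack
#'
#' @param env An [env_stack()].
#' @param shift A [scenario_shift()]; may only name climatic layers.
#' @return A new [env_stack()] with shifted climatic layers; edaphic layers
#'   and the nodata mask are bit-identical to the input.
#' @export
apply_scenario <- function(env, shift) {
  stopifnot(inherits(env, "env_stack"), inherits(shift, "scenario_shift"))
  touched <- union(names(shift$offset), names(shift$factor))
  bad <- setdiff(touched, climatic_layers(env))
  if (length(bad))
    stop("scenario may only shift climatic layers; offending: ",
         paste(bad, collapse = ", "))
  layers <- env$layers
  for (nm in touched) {
    f <- if (nm %in% names(shift$factor)) shift$factor[[nm]] else 1
    o <- if (nm %in% names(shift$offset)) shift$offset[[nm]] else 0
    layers[[nm]] <- layers[[nm]] * f + o
  }
  env_stack(env$grid, layers, env$variable_class, nodata_mask = env$nodata_mask)
}

#' Generate a categorical land-cover raster
#'
#' Classes are carved from the level sets of a single smoothed random field,
#' so each class forms contiguous patches and realized fractions match the
#' request up to rounding.
#'
#' @param grid A [grid_spec()].
#' @param class_fractions Named non-negative fractions summing to ~1, e.g.
#'   `c(forest = 0.4, cropland = 0.3, grassland = 0.2, urban = 0.1)`.
#' @param seed Integer seed.
#' @param smoothing Field kernel sd in cells (default 5).
#' @return Object of class `landcover_raster`: integer matrix `values`
#'   (codes 1..k), named `classes` vector mapping code to class name, `grid`.
#' @export
generate_landcover <- function(grid, class_fractions, seed, smoothing = 5) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(class_fractions) == 0) stop("class_fractions must be nonempty")
  if (is.null(names(class_fractions)) || any(names(class_fractions) == ""))
    stop("class_fractions must be named")
  if (any(class_fractions < 0)) stop("fractions must be >= 0")
  if (abs(sum(class_fractions) - 1) > 0.01)
    stop("fractions must sum to ~1")
  fr <- class_fractions / sum(class_fractions)
  with_seed(seed, {
    f <- smooth_field(matrix(stats::rnorm(grid$n_rows * grid$n_cols),
                             grid$n_rows, grid$n_cols), smoothing)
    n <- length(f)
    ord <- order(f)
    bounds <- round(cumsum(fr) * n)
    codes <- integer(n)
    lo <- 1L
    for (k in seq_along(fr)) {
      if (bounds[k] >= lo) codes[ord[lo:bounds[k]]] <- k
      lo <- bounds[k] + 1L
    }
    codes[codes == 0L] <- length(fr)  # rounding slack lands in the last class
    structure(list(values = matrix(codes, grid$n_rows, grid$n_cols),
                   classes = stats::setNames(seq_along(fr), names(fr)),
                   grid = grid),
              class = "landcover_raster")
  })
}

#' Write / read a land-cover raster (ASCII grid + YAML class sidecar)
#'
#' @param lc A [generate_landcover()] result.
#' @param dir Directory for `landcover.asc` and `landcover.yml`.
#' @return `dir` invisibly (writer); a `landcover_raster` (reader).
#' @export
write_landcover <- function(lc, dir) {
  stopifnot(inherits(lc, "landcover_raster"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ascii_grid(lc$values, lc$grid, file.path(dir, "landcover.asc"))
  yaml::write_yaml(list(classes = as.list(lc$classes)),
                   file.path(dir, "landcover.yml"))
  invisible(dir)
}

#' @rdname write_landcover
#' @export
read_landcover <- function(dir) {
  r <- read_ascii_grid(file.path(dir, "landcover.asc"))
  meta <- yaml::read_yaml(file.path(dir, "landcover.yml"))
  structure(list(values = r$values,
                 classes = unlist(meta$classes),
                 grid = r$grid),
            class = "landcover_raster")
}
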