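#' @title Occurrence quality control
#' @description A five-criterion cleaning cascade for presence records:
#'   (i) incomplete or invalid coordinates, (ii) points off land (ocean or
#'   outside the study grid), (iii) collection before the climate baseline
#'   year, (iv) climatically marginal locations (e.g. botanical gardens),
#'   (v) fossil/unknown-source records; followed by one-record-per-grid-cell
#'   thinning and a minimum-sample-size rule per species. Filters flag rows,
#'   never delete them, so a full audit report is reconstructible; a row is
#'   "retained" iff it carries no flag.
#' @name occurrence_qc
NULL

QC_FLAGS <- c("qc_bad_coord", "qc_off_land", "qc_pre_baseline",
              "qc_marginal_climate", "qc_unknown_source", "qc_thinned")

ensure_qc_cols <- function(table) {
  for (f in QC_FLAGS) if (is.null(table[[f]])) table[[f]] <- FALSE
  table
}

#' Which occurrence rows are retained (carry no QC flag)?
#'
#' @param table An occurrence data.frame, possibly flagged.
#' @return Logical vector, one element per row.
#' @export
qc_retained <- function(table) {
  table <- ensure_qc_cols(table)
  !Reduce(`|`, lapply(QC_FLAGS, function(f) table[[f]]))
}

#' Flag records with missing or out-of-range coordinates
#'
#' @param table Occurrence data.frame with `lon` and `lat` columns.
#' @return The table with `qc_bad_coord` set; no rows are dropped.
#' @export
filter_coordinates <- function(table) {
  stopifnot(nrow(table) >= 1)
  table <- ensure_qc_cols(table)
  bad <- !is.finite(table$lon) | !is.finite(table$lat) |
    table$lon < -180 | table$lon > 180 | table$lat < -90 | table$lat > 90
  table$qc_bad_coord <- table$qc_bad_coord | bad
  table
}

#' Flag records off land (nodata cells or outside the study grid)
#'
#' Only rows still retained are tested; rows already flagged (e.g. bad
#' coordinates) are left as they are.
#'
#' @param table Occurrence data.frame.
#' @param env An [env_stack()] whose nodata mask defines land.
#' @return The table with `qc_off_land` set.
#' @export
filter_land <- function(table, env) {
  stopifnot(inherits(env, "env_stack"))
  table <- ensure_qc_cols(table)
  cand <- qc_retained(table)
  idx <- cell_index(env$grid, table$lon, table$lat)
  off <- is.na(idx$row)
  on_grid <- !off
  if (any(on_grid)) {
    lin <- (idx$col[on_grid] - 1L) * env$grid$n_rows + idx$row[on_grid]
    off[on_grid] <- env$nodata_mask[lin]
  }
  table$qc_off_land <- table$qc_off_land | (cand & off)
  table
}

#' Flag records collected before the climate baseline
#'
#' Records dated before `baseline_year` do not match the baseline climate
#' normals and are flagged; the baseline year itself is retained. Missing
#' years are flagged by default (conservative).
#'
#' @param table Occurrence data.frame with a `year` column.
#' @param baseline_year First acceptable collection year (default 1969).
#' @param flag_missing Flag rows with missing year? (default TRUE)
#' @return The table with `qc_pre_baseline` set.
#' @export
filter_year <- function(table, baseline_year = 1969, flag_missing = TRUE) {
  table <- ensure_qc_cols(table)
  cand <- qc_retained(table)
  old <- !is.na(table$year) & table$year < baseline_year
  if (flag_missing) old <- old | is.na(table$year)
  table$qc_pre_baseline <- table$qc_pre_baseline | (cand & old)
  table
}

#' Flag records from blacklisted sources
#'
#' Fossil records and records of unknown provenance do not represent extant
#' wild populations under the baseline climate.
#'
#' @param table Occurrence data.frame with a `source` column.
#' @param blacklist Source labels to reject (default `c("fossil", "unknown")`).
#' @return The table with `qc_unknown_source` set.
#' @export
filter_source <- function(table, blacklist = c("fossil", "unknown")) {
  table <- ensure_qc_cols(table)
  cand <- qc_retained(table)
  bad <- !is.na(table$source) & table$source %in% blacklist
  table$qc_unknown_source <- table$qc_unknown_source | (cand & bad)
  table
}

#' Flag climatically marginal records
#'
#' Per species and per climatic layer, the empirical distribution of the
#' layer value over that species' currently retained records defines a
#' climatic gradient; records falling strictly outside the central
#' `1 - tail_fraction` of the distribution (`tail_fraction/2` per side) on
#' any layer are flagged. Species with fewer than `min_records` retained
#' records are skipped with a warning (their gradient is too poorly sampled
#' to define tails).
#'
#' @param table Occurrence data.frame.
#' @param env An [env_stack()].
#' @param layers Climatic layer names (default: all climatic layers in `env`).
#' @param tail_fraction Total tail mass treated as marginal (default 0.10,
#'   i.e. 5% per side).
#' @param min_records Minimum retained records per species (default 20).
#' @return The table with `qc_marginal_climate` set.
#' @export
filter_marginal_climate <- function(table, env, layers = NULL,
                                    tail_fraction = 0.10, min_records = 20) {
  stopifnot(inherits(env, "env_stack"),
            tail_fraction >= 0, tail_fraction < 1)
  if (is.null(layers)) layers <- climatic_layers(env)
  miss <- setdiff(layers, layer_names(env))
  if (length(miss))
    stop("layers missing from stack: ", paste(miss, collapse = ", "))
  table <- ensure_qc_cols(table)
  if (tail_fraction == 0) return(table)
  vals <- extract_env(env, table$lon, table$lat, layers)
  # the reference distribution is defined by the upstream filters only
  # (coordinates, land, baseline year), so the gradient does not shrink when
  # the cascade is re-run on its own output: the filter is idempotent
  cand <- !(table$qc_bad_coord | table$qc_off_land | table$qc_pre_baseline)
  for (sp in unique(table$species)) {
    rows <- which(table$species == sp & cand)
    if (length(rows) < min_records) {
      warning("species '", sp, "': only ", length(rows),
              " retained records; marginal-climate filter skipped")
      next
    }
    flag <- rep(FALSE, length(rows))
    for (nm in layers) {
      v <- vals[[nm]][rows]
      q <- stats::quantile(v, c(tail_fraction / 2, 1 - tail_fraction / 2),
                           na.rm = TRUE, names = FALSE)
      flag <- flag | (!is.na(v) & (v < q[1] | v > q[2]))
    }
    table$qc_marginal_climate[rows] <- table$qc_marginal_climate[rows] | flag
  }
  table
}

#' Thin records to one per species per grid cell
#'
#' Reduces sampling bias and spatial autocorrelation: within each
#' (species, cell) group of retained records exactly one survives. The
#' survivor is the record with the most recent collection year, ties broken
#' by lowest row index, so thinning is deterministic and idempotent.
#'
#' @param table Occurrence data.frame.
#' @param grid A [grid_spec()].
#' @return The table with `qc_thinned` set.
#' @export
thin_to_grid <- function(table, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  table <- ensure_qc_cols(table)
  cand <- which(qc_retained(table))
  if (!length(cand)) return(table)
  idx <- cell_index(grid, table$lon[cand], table$lat[cand])
  key <- paste(table$species[cand], idx$row, idx$col, sep = "\r")
  yr <- table$year[cand]
  yr[is.na(yr)] <- -Inf
  # order: within key, highest year first then lowest original index
  ord <- order(key, -yr, cand)
  keep_first <- !duplicated(key[ord])
  thinned <- logical(length(cand))
  thinned[ord] <- !keep_first
  table$qc_thinned[cand] <- thinned
  table
}

#' Apply the minimum-sample-size rule
#'
#' Species are modelled only when strictly more than `min_n` records survive
#' QC (the rule is strict: a species with exactly `min_n` retained records
#' is dropped).
#'
#' @param table Occurrence data.frame after the full QC cascade.
#' @param min_n Strict lower bound on retained records (default 60).
#' @return Character vector of retained species ids.
#' @export
apply_min_sample <- function(table, min_n = 60) {
  if (nrow(table) == 0) return(character())
  kept <- table$species[qc_retained(table)]
  counts <- table(kept)
  names(counts)[counts > min_n]
}

#' Run the full QC cascade
#'
#' Applies the filters in their canonical order — coordinates, land,
#' baseline year, marginal climate, source, grid thinning — each acting only
#' on rows still retained. Re-running the cascade on its own output changes
#' nothing.
#'
#' @param table Occurrence data.frame.
#' @param env An [env_stack()] (its grid is also the thinning grid).
#' @param baseline_year,tail_fraction,min_records,blacklist Filter
#'   parameters; see the individual filters.
#' @return The flagged table.
#' @export
run_qc <- function(table, env, baseline_year = 1969, tail_fraction = 0.10,
                   min_records = 20, blacklist = c("fossil", "unknown")) {
  table <- filter_coordinates(table)
  table <- filter_land(table, env)
  table <- filter_year(table, baseline_year)
  table <- filter_marginal_climate(table, env, tail_fraction = tail_fraction,
                                   min_records = min_records)
  table <- filter_source(table, blacklist)
  thin_to_grid(table, env$grid)
}

#' Per-species QC report
#'
#' @param table A flagged occurrence data.frame.
#' @return A data.frame with one row per species: input rows, counts flagged
#'   by each filter, and retained rows.
#' @export
qc_report <- function(table) {
  table <- ensure_qc_cols(table)
  sp <- unique(table$species)
  out <- data.frame(species = sp, n_input = NA_integer_)
  for (f in QC_FLAGS) out[[f]] <- NA_integer_
  out$n_retained <- NA_integer_
  for (i in seq_along(sp)) {
    sub <- table[table$species == sp[i], , drop = FALSE]
    out$n_input[i] <- nrow(sub)
    for (f in QC_FLAGS) out[[f]][i] <- sum(sub[[f]])
    out$n_retained[i] <- sum(qc_retained(sub))
  }
  out
}

#' Read / write occurrence tables as CSV
#'
#' Canonical columns: `species,lon,lat,year,source`; QC flag columns and the
#' synthetic `.truth` column round-trip when present.
#'
#' @param table Occurrence data.frame.
#' @param path CSV file path.
#' @return `path` invisibly (writer); a data.frame (reader).
#' @export
write_occurrences <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
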