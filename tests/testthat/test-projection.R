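# a quick fitted ensemble + stack shared across projection tests
proj_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- make_env(n_rows = 25, n_cols = 30, seed = 14)
      occ <- sample_occurrences(make_niche(), env, 60, seed = 1)
      pa <- sample_pseudoabsences(occ, env, n = 150, seed = 2)
      tr <- build_training_set(occ, pa, env, k = 4, seed = 3)
      m <- suppressWarnings(fit_ensemble(tr, algorithms = c("GLM", "RF"),
                                         seed = 1, hyper = fast_hyper))
      cache <<- list(env = env, model = m, training = tr)
    }
    cache
  }
})

test_that("projected maps agree with pointwise predictions and keep nodata", {
  fx <- proj_fixture()
  map <- predict_map(fx$model, fx$env)
  expect_true(all(is.na(map$values[fx$env$nodata_mask])))
  land <- which(!fx$env$nodata_mask)
  # spot-check cells against the in-memory prediction API
  pick <- land[c(1, 50, length(land))]
  rc <- arrayInd(pick, dim(map$values))
  newdata <- extract_env(fx$env, cell_center(fx$env$grid, rc[, 1], rc[, 2])$lon,
                         cell_center(fx$env$grid, rc[, 1], rc[, 2])$lat)
  expect_equal(map$values[pick], predict(fx$model, newdata))
})

test_that("missing predictors are rejected by name", {
  fx <- proj_fixture()
  env_small <- env_stack(fx$env$grid, fx$env$layers["BIO1"],
                         fx$env$variable_class["BIO1"],
                         fx$env$nodata_mask)
  expect_error(predict_map(fx$model, env_small), "BIO4")
})

test_that("a constant stack projects to a constant map", {
  fx <- proj_fixture()
  g <- grid_spec(8, 8)
  const <- env_stack(g, list(BIO1 = matrix(26, 8, 8),
                             BIO4 = matrix(120, 8, 8),
                             phh2o = matrix(58, 8, 8)),
                     fx$env$variable_class)
  map <- predict_map(fx$model, const)
  expect_equal(length(unique(as.vector(map$values))), 1)
})

test_that("GCM aggregation is the cellwise mean, bounded by its members", {
  fx <- proj_fixture()
  m1 <- predict_map(fx$model, fx$env)
  env2 <- apply_scenario(fx$env, scenario_shift("w", offset = c(BIO1 = 1)))
  m2 <- predict_map(fx$model, env2)
  agg <- aggregate_gcms(list(m1, m2), scenario = "future")
  expect_equal(agg$values, (m1$values + m2$values) / 2)
  expect_identical(aggregate_gcms(list(m1, m1))$values, m1$values)
  lo <- pmin(m1$values, m2$values); hi <- pmax(m1$values, m2$values)
  land <- which(!fx$env$nodata_mask)
  expect_true(all(agg$values[land] >= lo[land] - 1e-12))
  expect_true(all(agg$values[land] <= hi[land] + 1e-12))
  bad <- predict_map(fx$model, make_env(n_rows = 10, n_cols = 10, seed = 1))
  expect_error(aggregate_gcms(list(m1, bad)), "grid")
})

test_that("binarization counts match the suitability histogram", {
  fx <- proj_fixture()
  map <- predict_map(fx$model, fx$env)
  land <- which(!fx$env$nodata_mask)
  for (t in c(0.2, 0.5, 0.8)) {
    b <- binarize(map, t)
    expect_equal(sum(b$values, na.rm = TRUE), sum(map$values[land] >= t))
    expect_true(all(map$values[which(b$values)] >= t))
  }
  b_lo <- binarize(map, 1e-9)
  expect_equal(sum(b_lo$values, na.rm = TRUE), length(land))
  expect_error(binarize(map, 0), "threshold")
})

test_that("land-cover masking is a set intersection", {
  fx <- proj_fixture()
  g <- fx$env$grid
  map <- predict_map(fx$model, fx$env)
  b <- binarize(map, fx$model$threshold)
  lc <- generate_landcover(g, c(forest = 0.4, cropland = 0.35, urban = 0.25),
                           seed = 5)
  all_cls <- mask_landcover(b, lc, names(lc$classes))
  expect_equal(all_cls$values, b$values)
  none <- mask_landcover(b, lc, character())
  expect_false(any(none$values, na.rm = TRUE))
  crop <- mask_landcover(b, lc, "cropland")
  manual <- which(b$values & lc$values == lc$classes[["cropland"]])
  expect_setequal(which(crop$values), manual)
  expect_warning(mask_landcover(b, lc, c("cropland", "swamp")), "swamp")
})

test_that("area change satisfies the bookkeeping identities", {
  fx <- proj_fixture()
  map <- predict_map(fx$model, fx$env)
  b_cur <- binarize(map, fx$model$threshold)
  env_f <- apply_scenario(fx$env, scenario_shift("f", offset = c(BIO1 = 1.5)))
  b_fut <- binarize(predict_map(fx$model, env_f), fx$model$threshold)
  ac <- area_change(b_cur, b_fut)
  grid <- fx$env$grid
  area_of <- function(mask) {
    v <- mask; v[is.na(v)] <- FALSE
    sum(rowSums(v) * cell_area_km2(grid))
  }
  gain <- ac$change == 3L; stable <- ac$change == 2L; loss <- ac$change == 1L
  expect_equal(area_of(gain) + area_of(stable), ac$future_km2)
  expect_equal(area_of(loss) + area_of(stable), ac$current_km2)
  # identity scenario: no change
  ac0 <- area_change(b_cur, b_cur)
  expect_equal(ac0$pct_change, 0)
  # antisymmetry of the absolute change
  ac_rev <- area_change(b_fut, b_cur)
  expect_equal(ac_rev$future_km2 - ac_rev$current_km2,
               -(ac$future_km2 - ac$current_km2))
})

test_that("adding one equatorial-band cell changes area by its geodesic size", {
  g <- grid_spec(4, 4, x_min = 0, y_min = -2 * 2.5 / 60)  # straddles equator
  v <- matrix(FALSE, 4, 4); v[1, 1] <- TRUE
  cur <- binary_map("sp", "c", v, g, 0.5)
  v2 <- v; v2[2, 3] <- TRUE  # row 2 touches the equator from the north
  fut <- binary_map("sp", "f", v2, g, 0.5)
  ac <- area_change(cur, fut)
  expect_equal(ac$future_km2 - ac$current_km2, cell_area_km2(g)[2])
  expect_equal(ac$pct_change, 100 * cell_area_km2(g)[2] / cell_area_km2(g)[1])
})

test_that("geodesic areas depend on latitude, cell counts do not", {
  g <- grid_spec(10, 10, x_min = 0, y_min = 30)
  north <- matrix(FALSE, 10, 10); north[1, ] <- TRUE
  south <- matrix(FALSE, 10, 10); south[10, ] <- TRUE
  b_n <- binary_map("sp", "c", north, g, 0.5)
  b_s <- binary_map("sp", "c", south, g, 0.5)
  a_n <- area_change(b_n, b_n)$current_km2
  a_s <- area_change(b_s, b_s)$current_km2
  expect_lt(a_n, a_s)  # same cell count, higher latitude, smaller area
  c_n <- area_change(b_n, b_n, mode = "count")$current_km2
  c_s <- area_change(b_s, b_s, mode = "count")$current_km2
  expect_equal(c_n, c_s)
})

test_that("masked suitable area never exceeds the unmasked area", {
  fx <- proj_fixture()
  map <- predict_map(fx$model, fx$env)
  b_cur <- binarize(map, fx$model$threshold)
  env_f <- apply_scenario(fx$env, scenario_shift("f", offset = c(BIO4 = 20)))
  b_fut <- binarize(predict_map(fx$model, env_f), fx$model$threshold)
  lc <- generate_landcover(fx$env$grid,
                           c(forest = 0.5, cropland = 0.5), seed = 7)
  ac <- area_change(b_cur, b_fut, landcover = lc, allowed = "cropland")
  expect_lte(ac$masked_current_km2, ac$current_km2)
  expect_lte(ac$masked_future_km2, ac$future_km2)
})
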