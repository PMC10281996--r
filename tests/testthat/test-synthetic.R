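test_that("generated layers are deterministic and hit requested moments", {
  g <- grid_spec(100, 100, x_min = -10, y_min = 0)
  specs <- list(list(name = "a", class = "climatic", mean = 5, sd = 1,
                     smoothing = 2),
                list(name = "b", class = "edaphic", mean = -3, sd = 0.5,
                     smoothing = 0))
  e1 <- generate_env_stack(g, specs, seed = 7)
  e2 <- generate_env_stack(g, specs, seed = 7)
  expect_identical(e1$layers, e2$layers)
  e3 <- generate_env_stack(g, specs, seed = 8)
  expect_false(identical(e1$layers$a, e3$layers$a))
  # 10^4 cells: realized sd within 10% of request (here exact by rescaling)
  expect_lt(abs(sd(e1$layers$a) - 1), 0.1)
  expect_lt(abs(mean(e1$layers$a) - 5), 0.1)
  expect_lt(abs(sd(e1$layers$b) - 0.5), 0.05)
})

test_that("degenerate noise gives a constant layer at the mean", {
  g <- grid_spec(10, 10)
  e <- generate_env_stack(g, list(
    list(name = "flat", class = "climatic", mean = 3.5, sd = 0,
         smoothing = 0)), seed = 1)
  expect_true(all(e$layers$flat == 3.5))
})

test_that("stack generation rejects bad inputs", {
  g <- grid_spec(10, 10)
  expect_error(generate_env_stack(g, list(
    list(name = "x", class = "climatic", mean = 0, sd = 1),
    list(name = "x", class = "climatic", mean = 0, sd = 1)), seed = 1),
    "duplicate")
  expect_error(grid_spec(0, 5), "positive")
  expect_error(generate_env_stack(g, list(
    list(name = "x", class = "climatic", mean = 0, sd = 1,
         smoothing = -1)), seed = 1), "smoothing")
})

test_that("true suitability matches the closed-form Gaussian product", {
  env <- make_env(seed = 3)
  truth <- species_niche("sp", list(BIO4 = c(optimum = 110, tolerance = 30),
                                    BIO1 = c(optimum = 26, tolerance = 1.5)),
                         prevalence_target = 0.3)
  suit <- true_suitability(truth, env)
  land <- which(!env$nodata_mask)
  raw <- exp(-0.5 * ((env$layers$BIO4[land] - 110) / 30)^2) *
         exp(-0.5 * ((env$layers$BIO1[land] - 26) / 1.5)^2)
  expected <- pmin(raw * 0.3 / mean(raw), 1)
  # hand evaluation at 3 cells plus the whole-field identity
  for (i in c(1, 17, length(land)))
    expect_equal(suit$values[land[i]], expected[i])
  expect_equal(suit$values[land], expected)
  expect_equal(mean(suit$values[land]), 0.3, tolerance = 1e-6)
  expect_true(all(is.na(suit$values[env$nodata_mask])))
})

test_that("cell at all optima scores 1 before prevalence rescaling", {
  g <- grid_spec(5, 5)
  env <- env_stack(g, list(a = matrix(2, 5, 5)), c(a = "climatic"))
  truth <- species_niche("sp", list(a = c(optimum = 2, tolerance = 1)), 0.5)
  # flat layer at the optimum: raw response is 1 everywhere, so rescaling to
  # prevalence 0.5 caps gives exactly 0.5 everywhere
  suit <- true_suitability(truth, env)
  expect_true(all(suit$values == 0.5))
})

test_that("infinite tolerance on every other layer leaves response flat", {
  env <- make_env(seed = 4)
  truth <- species_niche("sp", list(BIO4 = c(optimum = 0, tolerance = Inf),
                                    BIO1 = c(optimum = 26, tolerance = 1)),
                         0.2)
  suit <- true_suitability(truth, env)
  land <- which(!env$nodata_mask)
  raw <- exp(-0.5 * ((env$layers$BIO1[land] - 26))^2)
  expect_equal(suit$values[land], pmin(raw * 0.2 / mean(raw), 1))
  expect_error(species_niche("sp", list(a = c(optimum = 0, tolerance = Inf)),
                             0.5), "finite tolerance")
})

test_that("missing response layer is rejected by name", {
  env <- make_env()
  truth <- species_niche("sp", list(BIO99 = c(optimum = 0, tolerance = 1)), 0.2)
  expect_error(true_suitability(truth, env), "BIO99")
})

test_that("occurrence sampling injects exactly the requested contamination", {
  env <- make_env(seed = 5)
  truth <- make_niche()
  occ <- sample_occurrences(truth, env, n_clean = 50,
                            contamination = list(n_ocean = 5, n_pre1969 = 7,
                                                 n_duplicates = 4,
                                                 n_marginal = 3,
                                                 n_unknown_source = 2),
                            seed = 9)
  expect_equal(as.vector(table(occ$.truth)[c("clean", "duplicate", "marginal",
                                             "ocean", "pre1969",
                                             "unknown_source")]),
               c(50, 4, 3, 5, 7, 2))
  # ocean records land on nodata cells, and only they do
  idx <- cell_index(env$grid, occ$lon, occ$lat)
  on_nodata <- env$nodata_mask[cbind(idx$row, idx$col)]
  expect_equal(sum(on_nodata), 5)
  expect_true(all(occ$.truth[on_nodata] == "ocean"))
  # clean records: on land, year >= 1969
  clean <- occ[occ$.truth == "clean", ]
  expect_true(all(clean$year >= 1969))
  expect_error(sample_occurrences(truth, env, 10,
                                  list(n_ocean = 1e6), seed = 1),
               "capacity")
})

test_that("contamination-free samples are clean and reproducible", {
  env <- make_env(seed = 6)
  truth <- make_niche()
  o1 <- sample_occurrences(truth, env, 80, seed = 2)
  o2 <- sample_occurrences(truth, env, 80, seed = 2)
  expect_identical(o1, o2)
  expect_true(all(o1$.truth == "clean"))
  idx <- cell_index(env$grid, o1$lon, o1$lat)
  expect_false(any(env$nodata_mask[cbind(idx$row, idx$col)]))
  expect_true(all(o1$year >= 1969))
})

test_that("occurrence sampling tracks suitability (binomial check)", {
  # uniform truth on a flat landscape: occupancy proportional to cell count
  g <- grid_spec(40, 50)
  env <- env_stack(g, list(a = matrix(1, 40, 50)), c(a = "climatic"))
  truth <- species_niche("sp", list(a = c(optimum = 1, tolerance = 5)), 0.5)
  occ <- sample_occurrences(truth, env, 10000, seed = 13)
  # split the grid into west/east halves: counts ~ Binomial(n, 1/2)
  west <- sum(occ$lon < g$x_min + g$n_cols / 2 * g$resolution)
  expect_lt(abs(west - 5000), 4 * sqrt(10000 * 0.25))
})

test_that("scenario shifts are affine on climatic layers only", {
  env <- make_env(seed = 8)
  land <- which(!env$nodata_mask)
  id <- scenario_shift("id", offset = c(BIO1 = 0), factor = c(BIO1 = 1))
  expect_equal(apply_scenario(env, id)$layers, env$layers)
  sh <- scenario_shift("warm", offset = c(BIO1 = 2))
  warmed <- apply_scenario(env, sh)
  expect_equal(mean(warmed$layers$BIO1[land]),
               mean(env$layers$BIO1[land]) + 2)
  expect_identical(warmed$layers$phh2o, env$layers$phh2o)
  half <- apply_scenario(env, scenario_shift("dry", factor = c(BIO4 = 0.5)))
  expect_equal(sd(half$layers$BIO4[land]), sd(env$layers$BIO4[land]) / 2)
  expect_error(apply_scenario(env, scenario_shift("bad",
                                                  offset = c(phh2o = 1))),
               "phh2o")
  expect_error(scenario_shift("bad", factor = c(BIO1 = 0)), "> 0")
})

test_that("land-cover classes hit requested fractions in contiguous patches", {
  g <- grid_spec(100, 100, x_min = -10, y_min = 0)
  lc <- generate_landcover(g, c(a = 0.5, b = 0.5), seed = 3)
  fr <- table(lc$values) / length(lc$values)
  expect_true(all(abs(fr - 0.5) < 0.05))
  lc2 <- generate_landcover(g, c(a = 0.5, b = 0.5), seed = 3)
  expect_identical(lc$values, lc2$values)
  one <- generate_landcover(g, c(only = 1), seed = 1)
  expect_true(all(one$values == 1))
  expect_error(generate_landcover(g, numeric(), seed = 1), "nonempty")
})

test_that("rasters and stacks round-trip through text formats", {
  env <- make_env(n_rows = 12, n_cols = 15, seed = 2)
  dir <- withr::local_tempdir()
  write_env_stack(env, dir)
  back <- read_env_stack(dir)
  expect_equal(back$layers, env$layers, tolerance = 1e-12)
  expect_equal(back$variable_class, env$variable_class)
  expect_equal(back$nodata_mask, env$nodata_mask)
  lc <- generate_landcover(env$grid, c(x = 0.3, y = 0.7), seed = 1)
  write_landcover(lc, dir)
  lc2 <- read_landcover(dir)
  expect_equal(lc2$values, lc$values)
  expect_equal(lc2$classes, lc$classes)
})
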