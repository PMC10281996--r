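occ_row <- function(lon, lat, year = 2000, species = "sp",
                    source = "field") {
  data.frame(species = species, lon = lon, lat = lat, year = year,
             source = source, stringsAsFactors = FALSE)
}

test_that("coordinate filter flags missing and out-of-range values only", {
  t <- rbind(occ_row(NA, 6.8), occ_row(-5.2, 91), occ_row(-5.2, 6.8),
             occ_row(181, 0), occ_row(0, NaN))
  f <- filter_coordinates(t)
  expect_equal(f$qc_bad_coord, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(nrow(f), nrow(t))  # flags, never drops
})

test_that("land filter flags exactly the injected ocean points", {
  env <- make_env(seed = 5)
  truth <- make_niche()
  occ <- sample_occurrences(truth, env, 40,
                            contamination = list(n_ocean = 5), seed = 4)
  f <- filter_land(filter_coordinates(occ), env)
  expect_equal(sum(f$qc_off_land), 5)
  expect_true(all(f$.truth[f$qc_off_land] == "ocean"))
  # points outside the grid extent count as off land
  out <- filter_land(filter_coordinates(occ_row(150, -40)), env)
  expect_true(out$qc_off_land)
})

test_that("baseline-year filter is strict before 1969 and keeps 1969", {
  t <- rbind(occ_row(0, 5, 1968), occ_row(0, 5, 1969), occ_row(0, 5, NA),
             occ_row(0, 5, 2010))
  f <- filter_year(t)
  expect_equal(f$qc_pre_baseline, c(TRUE, FALSE, TRUE, FALSE))
  f2 <- filter_year(t, flag_missing = FALSE)
  expect_equal(f2$qc_pre_baseline, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("source filter uses the configurable blacklist", {
  t <- rbind(occ_row(0, 5, source = "fossil"), occ_row(0, 5, source = "gbif"),
             occ_row(0, 5, source = "unknown"))
  f <- filter_source(t)
  expect_equal(f$qc_unknown_source, c(TRUE, FALSE, TRUE))
  f2 <- filter_source(t, blacklist = "gbif")
  expect_equal(f2$qc_unknown_source, c(FALSE, TRUE, FALSE))
})

test_that("marginal-climate filter matches a percentile oracle", {
  # 100 records along a single climatic gradient; with a 10% two-sided tail
  # the outermost records on either side are flagged, including the unique
  # maximum
  g <- grid_spec(1, 100, x_min = 0, y_min = 0)
  vals <- matrix(seq(1, 100), 1, 100)
  env <- env_stack(g, list(grad = vals), c(grad = "climatic"))
  ctr <- cell_center(g, rep(1, 100), 1:100)
  t <- occ_row(ctr$lon, ctr$lat)
  f <- filter_marginal_climate(t, env)
  v <- seq(1, 100)
  q <- quantile(v, c(0.05, 0.95), names = FALSE)
  expect_equal(f$qc_marginal_climate, v < q[1] | v > q[2])
  expect_true(f$qc_marginal_climate[100])  # the unique maximum
  # degenerate distribution: nothing to flag
  flat <- env_stack(g, list(grad = matrix(7, 1, 100)), c(grad = "climatic"))
  expect_false(any(filter_marginal_climate(t, flat)$qc_marginal_climate))
  # empty tail: no flags
  expect_false(any(filter_marginal_climate(t, env,
                                           tail_fraction = 0)$qc_marginal_climate))
  # too few records: skipped with a warning
  expect_warning(filter_marginal_climate(t[1:5, ], env),
                 "skipped")
  expect_error(filter_marginal_climate(t, env, layers = "nope"), "nope")
})

test_that("grid thinning keeps exactly one record per cell for any k", {
  g <- grid_spec(10, 10, x_min = 0, y_min = 0)
  ctr <- cell_center(g, 3, 3)
  for (k in 2:10) {
    t <- occ_row(rep(ctr$lon, k) + seq(0, 0.3, length.out = k) * g$resolution,
                 rep(ctr$lat, k), year = 1990 + seq_len(k))
    f <- thin_to_grid(t, g)
    expect_equal(sum(f$qc_thinned), k - 1)
    # the most recent year survives
    expect_equal(f$year[!f$qc_thinned], 1990 + k)
  }
  # distinct cells: nothing flagged
  sep <- occ_row(cell_center(g, 1:5, 1:5)$lon, cell_center(g, 1:5, 1:5)$lat)
  expect_false(any(thin_to_grid(sep, g)$qc_thinned))
  # tie on year: lowest input index survives; idempotent
  tie <- occ_row(c(ctr$lon, ctr$lon), c(ctr$lat, ctr$lat), year = c(2000, 2000))
  f <- thin_to_grid(tie, g)
  expect_equal(f$qc_thinned, c(FALSE, TRUE))
  expect_identical(thin_to_grid(f, g), f)
})

test_that("minimum-sample rule is strictly more than min_n", {
  t61 <- occ_row(seq_len(61) / 100, rep(5, 61), species = "keep")
  t60 <- occ_row(seq_len(60) / 100, rep(5, 60), species = "drop")
  both <- rbind(t61, t60)
  expect_equal(apply_min_sample(both), "keep")
  expect_equal(apply_min_sample(both[0, ]), character())
})

test_that("the full cascade is idempotent and conserves rows", {
  env <- make_env(seed = 6)
  truth <- make_niche()
  occ <- sample_occurrences(truth, env, 120,
                            contamination = list(n_ocean = 4, n_pre1969 = 6,
                                                 n_duplicates = 8,
                                                 n_unknown_source = 3),
                            seed = 2)
  f1 <- run_qc(occ, env)
  expect_equal(nrow(f1), nrow(occ))
  f2 <- run_qc(f1, env)
  expect_identical(f1[names(f1) != ".truth"], f2[names(f2) != ".truth"])
  # each injected class is caught by its filter (classes here are disjoint)
  expect_true(all(f1$qc_off_land[f1$.truth == "ocean"]))
  expect_true(all(f1$qc_pre_baseline[f1$.truth == "pre1969"]))
  rep <- qc_report(f1)
  expect_equal(rep$n_input, nrow(occ))
  expect_equal(rep$n_retained, sum(qc_retained(f1)))
})

test_that("occurrence tables round-trip through CSV", {
  env <- make_env(seed = 7)
  occ <- sample_occurrences(make_niche(), env, 20, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ, path)
  back <- read_occurrences(path)
  expect_equal(back$lon, occ$lon)
  expect_equal(back$.truth, occ$.truth)
})
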