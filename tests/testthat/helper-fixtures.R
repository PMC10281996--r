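# Shared in-code fixtures: small synthetic worlds sized for fast tests.

# three-layer stack (2 climatic, 1 edaphic) with a contiguous ocean
make_env <- function(n_rows = 30, n_cols = 40, seed = 11,
                     ocean_fraction = 0.15, x_min = -10, y_min = 4) {
  g <- grid_spec(n_rows, n_cols, x_min = x_min, y_min = y_min)
  generate_env_stack(g, list(
    list(name = "BIO1", class = "climatic", mean = 26, sd = 1.2,
         smoothing = 3, gradient = 0.5),
    list(name = "BIO4", class = "climatic", mean = 120, sd = 40,
         smoothing = 3),
    list(name = "phh2o", class = "edaphic", mean = 58, sd = 6, smoothing = 2)
  ), seed = seed, ocean_fraction = ocean_fraction)
}

# six-layer stack for niche-recovery style tests
make_env6 <- function(n_rows = 60, n_cols = 80, seed = 21,
                      ocean_fraction = 0.15) {
  g <- grid_spec(n_rows, n_cols, x_min = -14, y_min = 4)
  generate_env_stack(g, list(
    list(name = "BIO1", class = "climatic", mean = 26, sd = 1.2,
         smoothing = 4, gradient = 0.6),
    list(name = "BIO4", class = "climatic", mean = 120, sd = 40,
         smoothing = 4, gradient = -25),
    list(name = "BIO12", class = "climatic", mean = 1800, sd = 400,
         smoothing = 5),
    list(name = "BIO18", class = "climatic", mean = 350, sd = 120,
         smoothing = 5),
    list(name = "phh2o", class = "edaphic", mean = 58, sd = 6, smoothing = 3),
    list(name = "nitrogen", class = "edaphic", mean = 180, sd = 50,
         smoothing = 3)
  ), seed = seed, ocean_fraction = ocean_fraction)
}

make_niche <- function(id = "sp1", prevalence = 0.3) {
  species_niche(id, list(BIO4 = c(optimum = 110, tolerance = 30),
                         BIO1 = c(optimum = 26, tolerance = 1.5)),
                prevalence)
}

# cheap hyperparameters for tests exercising plumbing rather than accuracy
fast_hyper <- list(gbm_nrounds = 60, gbm_eta = 0.2, rf_ntree = 150)

# linearly separable 1-d toy classification set
separable_data <- function(n = 40, seed = 5) {
  set.seed(seed)
  data.frame(label = rep(c(1, 0), each = n),
             x1 = c(stats::runif(n, 1, 2), stats::runif(n, -2, -1)),
             x2 = stats::rnorm(2 * n))
}
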