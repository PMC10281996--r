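test_that("fold assignment is stratified, balanced and deterministic", {
  labels <- rep(c(1, 0), each = 8)
  f <- assign_folds(labels, k = 4, seed = 1)
  for (k in 1:4) {
    expect_equal(sum(f == k & labels == 1), 2)
    expect_equal(sum(f == k & labels == 0), 2)
  }
  expect_identical(f, assign_folds(labels, k = 4, seed = 1))
  # 10 presences over 4 folds: sizes 3,3,2,2 (remainder to low folds)
  lab2 <- c(rep(1, 10), rep(0, 8))
  f2 <- assign_folds(lab2, k = 4, seed = 2)
  expect_equal(as.vector(table(f2[lab2 == 1])), c(3, 3, 2, 2))
  expect_error(assign_folds(c(1, 1, 0, 0), k = 4), "at least k")
})

test_that("every algorithm separates a linearly separable toy set", {
  d <- separable_data()
  for (alg in c("GLM", "GAM", "GBM", "RF")) {
    fit <- suppressWarnings(fit_learner(alg, d, c("x1", "x2"), seed = 1,
                                        hyper = fast_hyper))
    expect_equal(auc(predict(fit, d), d$label), 1)
    p <- predict(fit, d)
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_error(fit_learner("GLM", transform(d, label = 1), c("x1", "x2")),
               "single class")
})

test_that("stochastic learners are reproducible under a fixed seed", {
  d <- separable_data(seed = 8)
  for (alg in c("GBM", "RF")) {
    f1 <- fit_learner(alg, d, c("x1", "x2"), seed = 3, hyper = fast_hyper)
    f2 <- fit_learner(alg, d, c("x1", "x2"), seed = 3, hyper = fast_hyper)
    expect_equal(predict(f1, d), predict(f2, d))
  }
})

test_that("CV AUC sits at chance when labels are independent of predictors", {
  set.seed(9)
  n <- 1000
  d <- data.frame(species = "null", lon = 0, lat = 0,
                  label = rbinom(n, 1, 0.5),
                  x1 = rnorm(n), x2 = rnorm(n))
  d$fold <- assign_folds(d$label, 4, seed = 1)
  tr <- structure(d, class = c("training_set", "data.frame"),
                  predictors = c("x1", "x2"))
  cv <- cross_validate(tr, algorithms = "GLM", seed = 1)
  expect_lt(abs(cv$mean_auc[["GLM"]] - 0.5), 0.05)
  # permutation null: TSS near zero as well
  expect_lt(abs(mean(cv$metrics$tss)), 0.1)
})

test_that("AUC weights follow the rescaled-skill rule", {
  expect_equal(unname(compute_weights(c(a = 0.8, b = 0.8))), c(0.5, 0.5))
  expect_equal(unname(compute_weights(c(a = 1.0, b = 0.5))), c(1, 0))
  expect_equal(unname(compute_weights(c(a = 0.9, b = 0.7))), c(2, 1) / 3)
  expect_error(compute_weights(c(a = 0.5, b = 0.45)), "no skillful")
  # literal mean-AUC mode
  expect_equal(unname(compute_weights(c(a = 0.9, b = 0.6), mode = "raw")),
               c(0.6, 0.4))
})

test_that("the ensemble is a convex combination of its members", {
  env <- make_env(n_rows = 30, n_cols = 40, seed = 12)
  occ <- sample_occurrences(make_niche(), env, 60, seed = 1)
  pa <- sample_pseudoabsences(occ, env, n = 120, seed = 2)
  tr <- build_training_set(occ, pa, env, k = 4, seed = 3)
  m <- fit_ensemble(tr, seed = 1, hyper = fast_hyper)
  expect_equal(sum(m$weights), 1, tolerance = 1e-9)
  sc <- predict(m, tr)
  members <- vapply(names(m$weights)[m$weights > 0],
                    function(a) predict(m$learners[[a]], tr),
                    numeric(nrow(tr)))
  expect_true(all(sc >= apply(members, 1, min) - 1e-12))
  expect_true(all(sc <= apply(members, 1, max) + 1e-12))
  expect_true(all(sc >= 0 & sc <= 1))
  # weighted mean identity at every point
  expect_equal(sc, as.numeric(members %*% m$weights[colnames(members)]))
})

test_that("single-algorithm and zero-weight ensembles behave as identities", {
  d <- separable_data(seed = 3)
  d <- cbind(data.frame(species = "sp", lon = 0, lat = 0), d)
  d$fold <- assign_folds(d$label, 4, seed = 1)
  tr <- structure(d, class = c("training_set", "data.frame"),
                  predictors = c("x1", "x2"))
  m1 <- suppressWarnings(fit_ensemble(tr, algorithms = "GLM", seed = 1))
  expect_equal(predict(m1, tr), predict(m1$learners$GLM, tr))
  # force a zero weight: predictions must ignore that member entirely
  m2 <- suppressWarnings(fit_ensemble(tr, weights = c(GLM = 1, RF = 0),
                                      seed = 1, hyper = fast_hyper))
  expect_equal(predict(m2, tr), predict(m2$learners$GLM, tr))
})

test_that("permutation importance concentrates on the active predictors", {
  set.seed(31)
  n <- 400
  d <- data.frame(species = "sp", lon = 0, lat = 0,
                  x1 = rnorm(n), x2 = rnorm(n), noise = rnorm(n))
  d$label <- rbinom(n, 1, plogis(3 * d$x1))
  d$label[1:2] <- c(0, 1)
  d$fold <- assign_folds(d$label, 4, seed = 1)
  tr <- structure(d, class = c("training_set", "data.frame"),
                  predictors = c("x1", "x2", "noise"))
  m <- suppressWarnings(fit_ensemble(tr, algorithms = c("GLM", "RF"),
                                     seed = 1, hyper = fast_hyper))
  vi <- variable_importance(m, tr,
                            c(x1 = "climatic", x2 = "climatic",
                              noise = "edaphic"),
                            n_permutations = 3, seed = 2)
  expect_equal(sum(vi$importance), 100, tolerance = 1e-9)
  expect_gt(vi$importance[["x1"]], 60)
  expect_lt(vi$importance[["noise"]], 20)
  expect_equal(sum(vi$class_sums), 100, tolerance = 1e-9)
  # class sums partition the per-variable importances
  expect_equal(vi$class_sums[["climatic"]],
               sum(vi$importance[c("x1", "x2")]))
})
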