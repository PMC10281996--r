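#' @title Consensus (ensemble) species distribution models
#' @description Four presence/pseudo-absence learners — logistic GLM with
#'   linear + quadratic terms, spline GAM, gradient-boosted trees (GBM) and
#'   random forest (RF) — are evaluated by fourfold cross-validation (AUC,
#'   TSS), refitted on all data, and combined as a weighted average of their
#'   suitability scores. Default weights rescale mean CV AUC by skill above
#'   chance (`max(AUC - 0.5, 0)`, renormalized); `mode = "raw"` uses mean
#'   AUC directly. Per-predictor relative importance is estimated by
#'   permutation on the best (highest mean CV AUC) algorithm.
#' @name sdm_ensemble
NULL

ALGORITHMS <- c("GLM", "GAM", "GBM", "RF")

default_hyper <- function() list(
  gbm_nrounds = 2000, gbm_eta = 0.01, gbm_depth = 3,
  rf_ntree = 500, gam_k = 4
)

#' Assign stratified cross-validation folds
#'
#' Presences and pseudo-absences are split separately so every fold contains
#' both classes; within each class fold sizes differ by at most one, with
#' remainders filling the lowest-numbered folds.
#'
#' @param labels Binary vector (1 presence, 0 pseudo-absence).
#' @param k Number of folds (default 4).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
assign_folds <- function(labels, k = 4, seed = 1) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% 0:1), k >= 2)
  if (sum(labels == 1) < k || sum(labels == 0) < k)
    stop("need at least k = ", k, " points of each class")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(1L, 0L)) {
      idx <- which(labels == cl)
      n <- length(idx)
      sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
      fold[sample(idx)] <- rep(seq_len(k), times = sizes)
    }
  })
  fold
}

#' Build a labelled training set from presences and pseudo-absences
#'
#' Extracts predictor values at every point, drops points with missing
#' extractions (off grid), and assigns stratified folds.
#'
#' @param presences Data.frame with `species`, `lon`, `lat` (retained
#'   records only).
#' @param pa A [sample_pseudoabsences()] result (or data.frame with
#'   `lon`/`lat`).
#' @param env An [env_stack()].
#' @param predictors Layer names to use (default: all layers in `env`).
#' @param k Folds (default 4).
#' @param seed Integer seed for fold assignment.
#' @return A data.frame of class `training_set`: `species`, `lon`, `lat`,
#'   `label`, `fold`, plus one column per predictor. Attribute `predictors`
#'   records the predictor names.
#' @export
build_training_set <- function(presences, pa, env, predictors = NULL,
                               k = 4, seed = 1) {
  stopifnot(inherits(env, "env_stack"))
  if (is.null(predictors)) predictors <- layer_names(env)
  pts <- bind_background(presences, pa)
  vals <- extract_env(env, pts$lon, pts$lat, predictors)
  ok <- stats::complete.cases(vals)
  pts <- pts[ok, , drop = FALSE]
  vals <- vals[ok, , drop = FALSE]
  label <- as.integer(pts$label == "presence")
  out <- cbind(
    data.frame(species = pts$species, lon = pts$lon, lat = pts$lat,
               label = label, fold = assign_folds(label, k, seed),
               stringsAsFactors = FALSE),
    vals)
  structure(out, class = c("training_set", "data.frame"),
            predictors = predictors)
}

#' Fit a single SDM learner
#'
#' All four algorithms return a scoring function into \[0, 1\] via
#' [predict.learner_fit()]. Hyperparameters are fixed and documented:
#' GLM = logistic regression with linear + quadratic terms; GAM = thin-plate
#' spline smoothers (basis dimension `gam_k`, REML); GBM = gradient-boosted
#' trees (`gbm_nrounds` rounds, learning rate `gbm_eta`, depth `gbm_depth`);
#' RF = `rf_ntree` classification trees. Stochastic learners (GBM, RF) are
#' seeded.
#'
#' @param algorithm One of `"GLM"`, `"GAM"`, `"GBM"`, `"RF"`.
#' @param data Data.frame containing `label` and the predictor columns.
#' @param predictors Predictor column names.
#' @param seed Integer seed for stochastic learners.
#' @param hyper Named list overriding [default hyperparameters].
#' @return An object of class `learner_fit`.
#' @export
fit_learner <- function(algorithm, data, predictors, seed = 1,
                        hyper = list()) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  hp <- utils::modifyList(default_hyper(), hyper)
  y <- as.integer(data$label)
  if (length(unique(y)) < 2)
    stop("degenerate training data: a single class")
  x <- as.matrix(data[, predictors, drop = FALSE])
  model <- with_seed(seed, switch(
    algorithm,
    GLM = {
      terms <- paste(c(predictors, sprintf("I(%s^2)", predictors)),
                     collapse = " + ")
      stats::glm(stats::as.formula(paste("label ~", terms)),
                 data = cbind(data.frame(label = y), as.data.frame(x)),
                 family = stats::binomial())
    },
    GAM = {
      sm <- vapply(predictors, function(p) {
        ku <- length(unique(x[, p]))
        if (ku > hp$gam_k) sprintf("s(%s, k = %d)", p, hp$gam_k) else p
      }, "")
      mgcv::gam(stats::as.formula(paste("label ~", paste(sm, collapse = " + "))),
                data = cbind(data.frame(label = y), as.data.frame(x)),
                family = stats::binomial(), method = "REML")
    },
    GBM = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = hp$gbm_depth,
                    eta = hp$gbm_eta, nthread = 1,
                    seed = seed %% .Machine$integer.max),
      data = xgboost::xgb.DMatrix(x, label = y),
      nrounds = hp$gbm_nrounds, verbose = 0),
    RF = randomForest::randomForest(x, factor(y, levels = 0:1),
                                    ntree = hp$rf_ntree)
  ))
  structure(list(algorithm = algorithm, model = model,
                 predictors = predictors, seed = seed, hyper = hp),
            class = "learner_fit")
}

#' Predict suitability scores from a fitted learner
#'
#' @param object A `learner_fit`.
#' @param newdata Data.frame containing the predictor columns.
#' @param ... Unused.
#' @return Numeric scores in \[0, 1\].
#' @export
predict.learner_fit <- function(object, newdata, ...) {
  x <- as.data.frame(newdata)[, object$predictors, drop = FALSE]
  p <- switch(object$algorithm,
    GLM = stats::predict(object$model, newdata = x, type = "response"),
    GAM = as.numeric(stats::predict(object$model, newdata = x,
                                    type = "response")),
    GBM = stats::predict(object$model, xgboost::xgb.DMatrix(as.matrix(x))),
    RF = stats::predict(object$model, as.matrix(x), type = "prob")[, "1"]
  )
  pmin(1, pmax(0, as.numeric(p)))
}

#' Cross-validate the candidate algorithms
#'
#' For each algorithm and each fold, fits on the other folds and scores the
#' held-out fold: AUC, plus TSS at the held-out-optimal threshold. Folds
#' where the held-out part has one class only yield `NA` metrics and are
#' dropped from the means.
#'
#' @param training A [build_training_set()] result (with `fold` column).
#' @param algorithms Algorithms to evaluate (default all four).
#' @param seed Base seed for stochastic learners.
#' @param hyper Hyperparameter overrides (see [fit_learner()]).
#' @return A list of class `cv_result`: `metrics` (data.frame algorithm /
#'   fold / auc / tss / threshold) and `mean_auc` (named vector).
#' @export
cross_validate <- function(training, algorithms = ALGORITHMS, seed = 1,
                           hyper = list()) {
  stopifnot(inherits(training, "training_set"))
  predictors <- attr(training, "predictors")
  folds <- sort(unique(training$fold))
  rows <- list()
  for (alg in algorithms) {
    for (f in folds) {
      test <- training[training$fold == f, , drop = FALSE]
      train <- training[training$fold != f, , drop = FALSE]
      if (length(unique(test$label)) < 2 || length(unique(train$label)) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          algorithm = alg, fold = f, auc = NA_real_, tss = NA_real_,
          threshold = NA_real_, stringsAsFactors = FALSE)
        next
      }
      fit <- fit_learner(alg, train, predictors, seed = seed + f,
                         hyper = hyper)
      sc <- predict(fit, test)
      m <- optimize_threshold(sc, test$label)
      rows[[length(rows) + 1]] <- data.frame(
        algorithm = alg, fold = f, auc = auc(sc, test$label), tss = m$tss,
        threshold = m$threshold, stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)
  mean_auc <- tapply(metrics$auc, metrics$algorithm, mean, na.rm = TRUE)
  mean_auc <- stats::setNames(as.numeric(mean_auc[algorithms]), algorithms)
  structure(list(metrics = metrics, mean_auc = mean_auc), class = "cv_result")
}

#' Ensemble weights from mean cross-validated AUC
#'
#' Default (`mode = "rescaled"`): `weight_a = max(AUC_a - 0.5, 0)`,
#' renormalized to sum 1, so algorithms at or below chance are excluded.
#' `mode = "raw"` renormalizes the mean AUCs themselves.
#'
#' @param mean_auc Named vector of mean CV AUCs per algorithm.
#' @param mode `"rescaled"` (default) or `"raw"`.
#' @return Named weights, nonnegative, summing to 1.
#' @export
compute_weights <- function(mean_auc, mode = c("rescaled", "raw")) {
  mode <- match.arg(mode)
  stopifnot(!is.null(names(mean_auc)))
  if (!any(mean_auc > 0.5, na.rm = TRUE))
    stop("no skillful model: every mean AUC is at or below chance (0.5)")
  w <- if (mode == "rescaled") pmax(mean_auc - 0.5, 0) else pmax(mean_auc, 0)
  w[is.na(w)] <- 0
  w / sum(w)
}

#' Fit the consensus ensemble for one species
#'
#' Runs fourfold cross-validation (unless `weights` are supplied), derives
#' AUC weights, refits every algorithm on all the data, and sets the
#' binarization threshold by maximizing sensitivity + specificity of the
#' ensemble scores on the full training set.
#'
#' @param training A [build_training_set()] result.
#' @param algorithms Algorithms to include (default all four).
#' @param weights Optional pre-computed named weights (skips CV weighting).
#' @param weight_mode Passed to [compute_weights()].
#' @param seed Integer seed.
#' @param hyper Hyperparameter overrides (see [fit_learner()]).
#' @return An object of class `ensemble_model`: `species_id`, `learners`,
#'   `weights`, `threshold`, `cv` (the `cv_result`), `best_algorithm`,
#'   `auc`/`tss` of the ensemble on the full training data, `predictors`.
#' @export
fit_ensemble <- function(training, algorithms = ALGORITHMS, weights = NULL,
                         weight_mode = c("rescaled", "raw"), seed = 1,
                         hyper = list()) {
  stopifnot(inherits(training, "training_set"))
  weight_mode <- match.arg(weight_mode)
  predictors <- attr(training, "predictors")
  cv <- NULL
  if (is.null(weights)) {
    cv <- cross_validate(training, algorithms, seed = seed, hyper = hyper)
    weights <- compute_weights(cv$mean_auc, mode = weight_mode)
  } else {
    stopifnot(!is.null(names(weights)), abs(sum(weights) - 1) < 1e-9)
    algorithms <- names(weights)
  }
  learners <- lapply(algorithms, function(alg)
    fit_learner(alg, training, predictors, seed = seed, hyper = hyper))
  names(learners) <- algorithms
  model <- structure(list(
    species_id = training$species[1], learners = learners,
    weights = weights, threshold = NA_real_, cv = cv,
    best_algorithm = if (!is.null(cv)) names(which.max(cv$mean_auc))
                     else names(which.max(weights)),
    predictors = predictors
  ), class = "ensemble_model")
  sc <- predict(model, training)
  m <- optimize_threshold(sc, training$label)
  model$threshold <- m$threshold
  model$tss <- m$tss
  model$auc <- auc(sc, training$label)
  model
}

#' Predict ensemble suitability
#'
#' Weighted average of the member learners' scores; zero-weight members are
#' skipped, so removing them changes no prediction.
#'
#' @param object An `ensemble_model`.
#' @param newdata Data.frame with the predictor columns.
#' @param ... Unused.
#' @return Numeric suitability in \[0, 1\].
#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  out <- numeric(nrow(as.data.frame(newdata)))
  for (alg in names(object$weights)) {
    w <- object$weights[[alg]]
    if (w > 0) out <- out + w * predict(object$learners[[alg]], newdata)
  }
  out
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("ensemble_model for", x$species_id, "\n weights:",
      paste(sprintf("%s=%.3f", names(x$weights), x$weights), collapse = ", "),
      "\n threshold:", format(x$threshold, digits = 3),
      " AUC:", format(x$auc, digits = 3),
      " TSS:", format(x$tss, digits = 3), "\n")
  invisible(x)
}

#' Permutation variable importance
#'
#' On the best algorithm (highest mean CV AUC), each predictor column is
#' permuted `n_permutations` times and the mean drop in training AUC
#' recorded; negative drops are truncated to zero and the result rescaled to
#' sum to 100%. Climatic and edaphic class sums partition the total.
#'
#' @param model An `ensemble_model`.
#' @param training The [build_training_set()] used to fit it.
#' @param variable_class Named map layer -> `"climatic"`/`"edaphic"`.
#' @param n_permutations Permutations per predictor (default 5).
#' @param seed Integer seed.
#' @return A list of class `variable_importance`: `species_id`, `algorithm`,
#'   `importance` (named %, sums to 100), `class_sums` (climatic/edaphic %).
#' @export
variable_importance <- function(model, training, variable_class,
                                n_permutations = 5, seed = 1) {
  stopifnot(inherits(model, "ensemble_model"), inherits(training, "training_set"))
  predictors <- model$predictors
  miss <- setdiff(predictors, names(variable_class))
  if (length(miss))
    stop("variable_class missing for: ", paste(miss, collapse = ", "))
  best <- model$learners[[model$best_algorithm]]
  base_auc <- auc(predict(best, training), training$label)
  drops <- with_seed(seed, {
    vapply(predictors, function(p) {
      mean(vapply(seq_len(n_permutations), function(i) {
        perm <- training
        perm[[p]] <- sample(perm[[p]])
        base_auc - auc(predict(best, perm), training$label)
      }, 0))
    }, 0)
  })
  drops <- pmax(drops, 0)
  imp <- if (sum(drops) > 0) 100 * drops / sum(drops)
         else stats::setNames(rep(100 / length(predictors), length(predictors)),
                              predictors)
  cls <- variable_class[predictors]
  class_sums <- c(climatic = sum(imp[cls == "climatic"]),
                  edaphic = sum(imp[cls == "edaphic"]))
  structure(list(species_id = model$species_id,
                 algorithm = model$best_algorithm,
                 importance = imp, class_sums = class_sums),
            class = "variable_importance")
}
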