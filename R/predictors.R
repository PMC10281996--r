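#' @title Collinearity-based predictor selection
#' @description Environmental predictor sets (19 bioclimatic + soil layers)
#'   are strongly collinear; models are fitted on a reduced set chosen in two
#'   stages: iterative variance-inflation-factor filtering (drop the worst
#'   column while any VIF exceeds the threshold, default 8), then pairwise
#'   Pearson filtering (while any |r| exceeds 0.7, drop the lower-priority
#'   member of the worst pair). Priority stands in for expert ecological
#'   ranking; by default a variable's priority is its mean absolute
#'   correlation with all other variables (lower = more distinct = kept).
#' @name predictor_selection
NULL

check_predictor_matrix <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop("predictor matrix needs unique column names")
  if (anyNA(x)) stop("predictor matrix must not contain missing values")
  if (ncol(x) < 2) stop("need at least 2 predictors")
  if (nrow(x) <= ncol(x) + 1) stop("need more rows than predictors + 1")
  x
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing column `j`
#' on all the others. Perfectly collinear columns get `Inf` rather than an
#' error.
#'
#' @param x Numeric matrix or data.frame of predictors (named columns, no
#'   missing values).
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
compute_vif <- function(x) {
  x <- check_predictor_matrix(x)
  if (any(apply(x, 2, stats::sd) == 0))
    stop("constant predictor column")
  vif <- vapply(seq_len(ncol(x)), function(j) {
    r2 <- summary(stats::lm(x[, j] ~ x[, -j, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(vif) <- colnames(x)
  vif
}

# Default priority: rank by mean |r| to all other variables, ascending
# (rank 1 = most distinct = highest priority). Ties by column order.
default_priority <- function(x) {
  x <- as.matrix(x)
  r <- abs(stats::cor(x))
  diag(r) <- NA
  mean_r <- rowMeans(r, na.rm = TRUE)
  pr <- rank(mean_r, ties.method = "first")
  names(pr) <- colnames(x)
  pr
}

selection_result <- function(kept, dropped, priority) {
  structure(list(kept = kept, dropped = dropped, priority = priority),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result:", length(x$kept), "kept,", nrow(x$dropped), "dropped\n")
  cat(" kept:", paste(x$kept, collapse = ", "), "\n")
  if (nrow(x$dropped))
    print(x$dropped, row.names = FALSE)
  invisible(x)
}

#' Iterative VIF filtering
#'
#' While any column's VIF exceeds `threshold`, drop the single column with
#' the highest VIF (ties broken against the lower-priority name), then
#' recompute. Stops with a warning rather than reducing below 2 columns.
#'
#' @param x Predictor matrix/data.frame.
#' @param threshold VIF cutoff (default 8); columns are removed while any
#'   VIF exceeds it.
#' @param priority Named rank vector (1 = highest priority); default from
#'   mean absolute correlation.
#' @return A `selection_result`: `kept` (ordered names), `dropped`
#'   (data.frame name/stage/statistic), `priority`.
#' @export
vif_filter <- function(x, threshold = 8, priority = NULL) {
  x <- check_predictor_matrix(x)
  if (is.null(priority)) priority <- default_priority(x)
  dropped <- data.frame(name = character(), stage = character(),
                        statistic = numeric(), stringsAsFactors = FALSE)
  repeat {
    vif <- compute_vif(x)
    if (max(vif) <= threshold) break
    worst <- which(vif == max(vif))
    if (length(worst) > 1) {
      # drop the lowest-priority (largest rank) among the tied worst
      worst <- worst[which.max(priority[names(vif)[worst]])]
    }
    nm <- names(vif)[worst]
    dropped <- rbind(dropped, data.frame(name = nm, stage = "vif",
                                         statistic = unname(vif[worst]),
                                         stringsAsFactors = FALSE))
    x <- x[, setdiff(colnames(x), nm), drop = FALSE]
    if (ncol(x) < 2) {
      warning("VIF filter stopped: fewer than 2 predictors remain")
      break
    }
  }
  selection_result(colnames(x), dropped, priority)
}

#' Pairwise correlation filtering
#'
#' While any pair of columns has `|Pearson r| > r_max`, drop the
#' lower-priority member of the worst (highest |r|) pair.
#'
#' @param x Predictor matrix/data.frame (typically post-VIF).
#' @param r_max Absolute correlation cutoff (default 0.7).
#' @param priority Named rank vector (1 = highest priority); default from
#'   mean absolute correlation of the input.
#' @return A `selection_result` with stage `"correlation"` drops.
#' @export
correlation_filter <- function(x, r_max = 0.7, priority = NULL) {
  x <- check_predictor_matrix(x)
  if (is.null(priority)) priority <- default_priority(x)
  dropped <- data.frame(name = character(), stage = character(),
                        statistic = numeric(), stringsAsFactors = FALSE)
  repeat {
    if (ncol(x) < 2) break
    r <- stats::cor(x)
    diag(r) <- 0
    worst <- max(abs(r))
    if (worst <= r_max) break
    ij <- which(abs(r) == worst, arr.ind = TRUE)[1, ]
    pair <- colnames(x)[ij]
    # keep the higher-priority (smaller rank) member
    drop_nm <- pair[which.max(priority[pair])]
    dropped <- rbind(dropped, data.frame(name = drop_nm, stage = "correlation",
                                         statistic = worst,
                                         stringsAsFactors = FALSE))
    x <- x[, setdiff(colnames(x), drop_nm), drop = FALSE]
  }
  selection_result(colnames(x), dropped, priority)
}

#' Full two-stage predictor selection
#'
#' VIF filtering followed by pairwise correlation filtering; the final kept
#' set satisfies both thresholds simultaneously.
#'
#' @param x Predictor matrix/data.frame: rows = training locations
#'   (presences and pseudo-absences pooled over species), columns =
#'   candidate layers.
#' @param vif_threshold VIF cutoff (default 8).
#' @param r_max Absolute pairwise correlation cutoff (default 0.7).
#' @param priority Named rank vector; default from mean absolute correlation
#'   of the full input matrix.
#' @return A `selection_result` with drops from both stages.
#' @export
select_predictors <- function(x, vif_threshold = 8, r_max = 0.7,
                              priority = NULL) {
  x <- check_predictor_matrix(x)
  if (is.null(priority)) priority <- default_priority(x)
  s1 <- vif_filter(x, vif_threshold, priority)
  s2 <- correlation_filter(x[, s1$kept, drop = FALSE], r_max, priority)
  selection_result(s2$kept, rbind(s1$dropped, s2$dropped), priority)
}
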