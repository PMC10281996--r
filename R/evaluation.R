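#' @title Model evaluation: AUC, TSS and threshold optimization
#' @description Rank-based AUC (Mann-Whitney formulation, ties counted 0.5),
#'   confusion-matrix sensitivity/specificity, the true skill statistic
#'   TSS = sensitivity + specificity - 1, and the threshold that maximizes
#'   sensitivity + specificity (equivalently TSS), used to binarize
#'   continuous suitability predictions.
#' @name evaluation
NULL

check_scored <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), length(scores) >= 2)
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels must not be NA")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  labels
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random presence scores
#' higher than a random absence, ties counted 1/2. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = presence, 0 = absence); both classes
#'   must be present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- check_scored(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity, specificity and TSS at a threshold
#'
#' Predictions are positive iff `score >= threshold` (closed on the
#' positive side).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels; both classes must be present.
#' @param threshold Classification threshold.
#' @return A list of class `threshold_metrics`: `threshold`, `sensitivity`,
#'   `specificity`, `tss`.
#' @export
tss_at <- function(scores, labels, threshold) {
  labels <- check_scored(scores, labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0)
  fp <- sum(pred & labels == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(list(threshold = threshold, sensitivity = sens,
                 specificity = spec, tss = sens + spec - 1),
            class = "threshold_metrics")
}

#' @export
print.threshold_metrics <- function(x, ...) {
  cat(sprintf("threshold %.4g: sensitivity %.3f, specificity %.3f, TSS %.3f\n",
              x$threshold, x$sensitivity, x$specificity, x$tss))
  invisible(x)
}

#' Threshold maximizing sensitivity + specificity
#'
#' All distinct classification outcomes are realized by thresholds at the
#' distinct score values (prediction positive iff score >= t), plus one
#' class above the maximum. The threshold interval achieving the maximal
#' sensitivity + specificity is located exhaustively; the returned threshold
#' is the midpoint of that interval (ties across intervals resolved toward
#' the lowest, favouring sensitivity), clamped to (0, 1) for probability
#' scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels; both classes must be present.
#' @return A `threshold_metrics` list (see [tss_at()]).
#' @export
optimize_threshold <- function(scores, labels) {
  labels <- check_scored(scores, labels)
  u <- sort(unique(scores))
  # candidate thresholds: each distinct score (>= keeps it positive), plus
  # one past the maximum (nothing positive)
  cand <- c(u, u[length(u)] + 1)
  tss <- vapply(cand, function(t) {
    m <- tss_at(scores, labels, t)
    m$sensitivity + m$specificity
  }, 0)
  best <- which.max(tss)  # first maximum = lowest threshold class
  t_best <- cand[best]
  lo <- if (best == 1) t_best - 1 else cand[best - 1]
  mid <- (lo + t_best) / 2
  if (all(scores >= 0 & scores <= 1)) mid <- min(max(mid, 1e-9), 1 - 1e-9)
  out <- tss_at(scores, labels, mid)
  # clamping into (0,1) can push the midpoint out of its optimal interval
  # (e.g. scores of exactly 0); fall back to the candidate itself then
  if (out$sensitivity + out$specificity < tss[best] - 1e-12)
    out <- tss_at(scores, labels, t_best)
  out
}
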