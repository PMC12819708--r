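#' Empirical ROC analysis with tie-aware AUC
#'
#' Operating points are realised marker values under the inclusive
#' positivity rule (`hs_crp >= threshold`); the AUC is the Mann-Whitney
#' probability that a random reference-positive outranks a random
#' reference-negative, ties counting 0.5, which equals the trapezoidal
#' area under the empirical curve exactly.
#'
#' @name roc_analysis
NULL

#' Empirical ROC curve
#'
#' @param cohort A validated cohort with at least one reference-positive
#'   and one reference-negative subject.
#' @param positive_rule Reference predicate (default: severe pain).
#' @return A `roc_curve` list: `operating_points` (data frame with
#'   `threshold`, `fpr`, `tpr`, ordered from the all-negative point (0,0)
#'   at threshold `Inf` down to (1,1) at the smallest marker value),
#'   `auc`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc <- empirical_roc(canonical_fixture())
#' roc$auc
empirical_roc <- function(cohort, positive_rule = function(d) d$pain_category >= 3) {
  validate_cohort(cohort)
  ref <- positive_rule(as.data.frame(cohort))
  pos <- cohort$hs_crp[ref]
  neg <- cohort$hs_crp[!ref]
  if (length(pos) == 0 || length(neg) == 0) {
    abort_validation("ROC needs both reference classes present", "pulpdx_single_class")
  }
  thresholds <- c(Inf, sort(unique(cohort$hs_crp), decreasing = TRUE))
  op <- data.frame(
    threshold = thresholds,
    fpr = vapply(thresholds, function(t) mean(neg >= t), numeric(1)),
    tpr = vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  )
  structure(
    list(operating_points = op,
         auc = auc_mann_whitney(pos, neg),
         n_pos = length(pos), n_neg = length(neg)),
    class = "roc_curve"
  )
}

#' Mann-Whitney AUC
#'
#' Mean over all positive x negative pairs of 1 (positive larger), 0.5
#' (tied) or 0 — computed via the rank-sum identity, O(n log n).
#'
#' @param pos_values Marker values of reference-positive subjects.
#' @param neg_values Marker values of reference-negative subjects.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(pos_values, neg_values) {
  n_pos <- length(pos_values)
  n_neg <- length(neg_values)
  if (n_pos == 0 || n_neg == 0) {
    abort_validation("both groups must be non-empty", "pulpdx_single_class")
  }
  r <- rank(c(pos_values, neg_values))  # mid-ranks: ties count 0.5
  n_pos <- as.numeric(n_pos)            # avoid integer overflow at large n
  n_neg <- as.numeric(n_neg)
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Trapezoidal area under an ROC curve; used as the geometric route that
# must agree with the rank route to machine precision.
trapezoid_auc <- function(roc) {
  op <- roc$operating_points[order(roc$operating_points$fpr,
                                   roc$operating_points$tpr), ]
  sum(diff(op$fpr) * (utils::head(op$tpr, -1) + utils::tail(op$tpr, -1)) / 2)
}

#' Stratified percentile bootstrap CI for the AUC
#'
#' Resamples with replacement within each reference class (so every
#' resample keeps both classes), recomputes the Mann-Whitney AUC, and
#' takes the percentile interval.
#'
#' @param cohort A validated cohort.
#' @param b Number of bootstrap resamples (`>= 100`).
#' @param confidence Confidence level.
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param positive_rule Reference predicate.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
auc_bootstrap_ci <- function(cohort, b = 10000, confidence = 0.95,
                             seed = 20250307,
                             positive_rule = function(d) d$pain_category >= 3) {
  if (b < 100) abort_validation("b must be >= 100", "pulpdx_bad_value")
  validate_cohort(cohort)
  ref <- positive_rule(as.data.frame(cohort))
  pos <- cohort$hs_crp[ref]
  neg <- cohort$hs_crp[!ref]
  if (length(pos) == 0 || length(neg) == 0) {
    abort_validation("ROC needs both reference classes present", "pulpdx_single_class")
  }
  aucs <- with_seed(seed, {
    vapply(seq_len(b), function(i) {
      auc_mann_whitney(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    }, numeric(1))
  })
  alpha <- 1 - confidence
  q <- stats::quantile(aucs, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Youden-optimal operating point
#'
#' Maximises J = tpr - fpr over the realised operating points; ties are
#' broken toward the larger threshold, favouring specificity.
#'
#' @param roc A `roc_curve` from [empirical_roc()].
#' @return A list `(threshold, j, tpr, fpr)`.
#' @export
youden_optimal <- function(roc) {
  op <- roc$operating_points
  j <- op$tpr - op$fpr
  finite <- is.finite(op$threshold)
  if (!any(finite)) abort_validation("degenerate ROC curve", "pulpdx_bad_value")
  best_j <- max(j[finite])
  idx <- which(finite & j == best_j)
  pick <- idx[which.max(op$threshold[idx])]
  list(threshold = op$threshold[pick], j = best_j,
       tpr = op$tpr[pick], fpr = op$fpr[pick])
}
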