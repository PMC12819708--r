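#' Threshold classification and 2x2 diagnostic metrics
#'
#' The index test is the pulpal-blood hs-CRP concentration dichotomised at
#' a threshold (positivity is inclusive: `hs_crp >= threshold`, matching
#' the clinical rule "hs-CRP >= 3.4 mg/L"); the reference standard is the
#' ordinal clinical pain category binarised at severe (`pain_category >=
#' 3`) unless another predicate is supplied.
#'
#' @name diagnostic_metrics
NULL

#' Construct a 2x2 confusion table
#'
#' @param tp,fp,fn,tn Non-negative cell counts (test vs reference).
#' @return A `confusion_table` list with a `degenerate` flag set when the
#'   reference has only one class.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != floor(cells))) {
    abort_validation("confusion table cells must be non-negative integers",
                     "pulpdx_bad_value")
  }
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         n = tp + fp + fn + tn,
         degenerate = (tp + fn == 0) || (fp + tn == 0)),
    class = "confusion_table"
  )
}

#' Classify a cohort at a threshold
#'
#' @param cohort A validated cohort.
#' @param threshold Positivity threshold (mg/L); test-positive iff
#'   `hs_crp >= threshold`.
#' @param positive_rule Reference predicate: a function of the cohort data
#'   frame returning a logical vector. Default: severe pain,
#'   `pain_category >= 3`.
#' @return A [confusion_table()]. A single-class reference yields a table
#'   flagged `degenerate` rather than an error; downstream proportions with
#'   zero denominators come back undefined.
#' @export
#' @examples
#' classify_at_threshold(canonical_fixture(), 2.9)
classify_at_threshold <- function(cohort, threshold,
                                  positive_rule = function(d) d$pain_category >= 3) {
  validate_cohort(cohort)
  if (threshold < 0) abort_validation("threshold must be >= 0", "pulpdx_bad_value")
  ref <- positive_rule(as.data.frame(cohort))
  test <- cohort$hs_crp >= threshold
  confusion_table(
    tp = sum(test & ref), fp = sum(test & !ref),
    fn = sum(!test & ref), tn = sum(!test & !ref)
  )
}

#' Wilson score interval for a binomial proportion
#'
#' Closed-form score interval. For 6 successes in 6 trials at 95% the
#' lower bound is `n / (n + z^2)` = 0.6097, the "61%" style bound seen in
#' small-sample diagnostic tables.
#'
#' @param successes,trials Counts, `0 <= successes <= trials`, `trials >= 1`.
#' @param confidence Confidence level in (0, 1).
#' @return A `proportion_ci` list: `estimate`, `lower`, `upper`, `method`,
#'   `confidence`, `successes`, `trials`.
#' @export
wilson_interval <- function(successes, trials, confidence = 0.95) {
  check_binom_args(successes, trials, confidence)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / trials
  denom <- trials + z^2
  center <- (successes + z^2 / 2) / denom
  half <- z * sqrt(successes * (trials - successes) / trials + z^2 / 4) / denom
  proportion_ci(p, max(0, center - half), min(1, center + half),
                "wilson", confidence, successes, trials)
}

#' Clopper-Pearson exact interval for a binomial proportion
#'
#' Exact interval by inverting binomial tail probabilities (beta
#' quantiles). For 6/6 at 95% the lower bound is `0.025^(1/6)` = 0.5407,
#' the "54%" style bound.
#'
#' @inheritParams wilson_interval
#' @return A `proportion_ci` list.
#' @export
clopper_pearson_interval <- function(successes, trials, confidence = 0.95) {
  check_binom_args(successes, trials, confidence)
  alpha <- 1 - confidence
  lower <- if (successes == 0) 0 else stats::qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  proportion_ci(successes / trials, lower, upper,
                "clopper_pearson", confidence, successes, trials)
}

check_binom_args <- function(successes, trials, confidence) {
  if (trials < 1) abort_validation("trials must be >= 1", "pulpdx_bad_value")
  if (successes < 0 || successes > trials) {
    abort_validation("successes must lie in [0, trials]", "pulpdx_bad_value")
  }
  if (!is_prob(confidence) || confidence <= 0 || confidence >= 1) {
    abort_validation("confidence must lie in (0, 1)", "pulpdx_bad_value")
  }
}

proportion_ci <- function(estimate, lower, upper, method, confidence,
                          successes = NA_integer_, trials = NA_integer_) {
  structure(
    list(estimate = estimate, lower = lower, upper = upper,
         method = method, confidence = confidence,
         successes = successes, trials = trials),
    class = "proportion_ci"
  )
}

undefined_proportion <- function(method, confidence, reason) {
  structure(
    list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
         method = method, confidence = confidence,
         successes = NA_integer_, trials = 0L, reason = reason),
    class = "proportion_ci"
  )
}

#' Sensitivity, specificity and predictive values with intervals
#'
#' Se = tp/(tp+fn), Sp = tn/(tn+fp), PPV = tp/(tp+fp), NPV = tn/(tn+fn),
#' each with the requested binomial interval. A zero denominator makes
#' that proportion undefined (with a reason) and leaves the others
#' untouched.
#'
#' @param ct A [confusion_table()].
#' @param method `"wilson"` or `"clopper_pearson"`.
#' @param confidence Confidence level.
#' @return A list of four `proportion_ci`: `sensitivity`, `specificity`,
#'   `ppv`, `npv`.
#' @export
proportion_metrics <- function(ct, method = c("wilson", "clopper_pearson"),
                               confidence = 0.95) {
  method <- match.arg(method)
  interval <- switch(method,
                     wilson = wilson_interval,
                     clopper_pearson = clopper_pearson_interval)
  one <- function(successes, trials, what) {
    if (trials == 0) return(undefined_proportion(method, confidence,
                                                 sprintf("no %s", what)))
    interval(successes, trials, confidence)
  }
  list(
    sensitivity = one(ct$tp, ct$tp + ct$fn, "reference-positive subjects"),
    specificity = one(ct$tn, ct$tn + ct$fp, "reference-negative subjects"),
    ppv = one(ct$tp, ct$tp + ct$fp, "test-positive subjects"),
    npv = one(ct$tn, ct$tn + ct$fn, "test-negative subjects")
  )
}

#' Likelihood ratios with log-method confidence intervals
#'
#' LR+ = Se/(1-Sp), LR- = (1-Se)/Sp. Confidence intervals use the
#' log-method with standard errors
#' `sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn))` for LR+ and
#' `sqrt(1/fn - 1/(tp+fn) + 1/tn - 1/(fp+tn))` for LR-. Under the
#' `"exact"` policy a zero numerator gives LR = 0 exactly with an
#' undefined CI, and a zero denominator gives an infinite LR (flagged, not
#' an error); under `"haldane"` 0.5 is added to every cell first.
#'
#' @param ct A [confusion_table()].
#' @param zero_cell_policy `"exact"` or `"haldane"`.
#' @param confidence Confidence level for the log-method intervals.
#' @return A list with `lr_pos` and `lr_neg`, each a list
#'   `(estimate, lower, upper, finite)`, plus the policy used.
#' @export
likelihood_ratios <- function(ct, zero_cell_policy = c("exact", "haldane"),
                              confidence = 0.95) {
  zero_cell_policy <- match.arg(zero_cell_policy)
  cells <- c(ct$tp, ct$fp, ct$fn, ct$tn)
  if (zero_cell_policy == "haldane") cells <- cells + 0.5
  tp <- cells[1]; fp <- cells[2]; fn <- cells[3]; tn <- cells[4]
  z <- stats::qnorm(1 - (1 - confidence) / 2)

  one_lr <- function(num_rate, den_rate, a, m, b, k) {
    # LR = num_rate / den_rate with a/m and b/k the two binomial fractions
    if (den_rate == 0) {
      if (num_rate == 0) {
        # 0/0: undefined, not infinite
        return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                    finite = FALSE))
      }
      return(list(estimate = Inf, lower = NA_real_, upper = NA_real_, finite = FALSE))
    }
    est <- num_rate / den_rate
    if (a == 0 || b == 0) {
      # zero numerator (LR exactly 0) or undefined log-SE
      return(list(estimate = est, lower = NA_real_, upper = NA_real_, finite = TRUE))
    }
    se <- sqrt(1 / a - 1 / m + 1 / b - 1 / k)
    list(estimate = est, lower = est * exp(-z * se), upper = est * exp(z * se),
         finite = TRUE)
  }

  npos <- tp + fn
  nneg <- fp + tn
  se_rate <- if (npos > 0) tp / npos else NA_real_
  sp_rate <- if (nneg > 0) tn / nneg else NA_real_
  lr_pos <- if (is.na(se_rate) || is.na(sp_rate)) {
    list(estimate = NA_real_, lower = NA_real_, upper = NA_real_, finite = FALSE)
  } else {
    one_lr(se_rate, 1 - sp_rate, tp, npos, fp, nneg)
  }
  lr_neg <- if (is.na(se_rate) || is.na(sp_rate)) {
    list(estimate = NA_real_, lower = NA_real_, upper = NA_real_, finite = FALSE)
  } else {
    one_lr(1 - se_rate, sp_rate, fn, npos, tn, nneg)
  }
  list(lr_pos = lr_pos, lr_neg = lr_neg, policy = zero_cell_policy,
       confidence = confidence)
}

#' Bayesian post-test probability
#'
#' Odds-form Bayes update: posterior odds = prior odds x LR, so
#' `posterior = pretest * lr / (pretest * lr + 1 - pretest)`. When the
#' pretest probability is the sample prevalence and `lr` the sample LR+,
#' the result equals the PPV (and with LR- it equals 1 - NPV).
#'
#' @param pretest Pre-test probability, strictly inside (0, 1).
#' @param lr Likelihood ratio, `>= 0` (may be `Inf`, giving probability 1).
#' @return The post-test probability.
#' @export
#' @examples
#' posttest_probability(6 / 13, 7)  # 0.857: "46% pretest -> 86% posttest"
posttest_probability <- function(pretest, lr) {
  if (!is.numeric(pretest) || any(pretest <= 0) || any(pretest >= 1)) {
    abort_validation("pretest probability must lie strictly in (0, 1)",
                     "pulpdx_bad_value")
  }
  if (any(lr < 0, na.rm = TRUE)) {
    abort_validation("likelihood ratio must be >= 0", "pulpdx_bad_value")
  }
  ifelse(is.infinite(lr), 1, pretest * lr / (pretest * lr + 1 - pretest))
}

#' Multi-threshold diagnostic report
#'
#' One metric set per threshold, in input order: the 2x2 table,
#' Se/Sp/PPV/NPV with the requested interval, likelihood ratios with
#' log-method CIs, and post-test probabilities computed from the sample
#' prevalence (so `posttest_pos` equals the PPV by the Bayes identity).
#'
#' @param cohort A validated cohort.
#' @param thresholds Numeric vector of thresholds (mg/L), non-empty.
#' @param ci_method `"wilson"` or `"clopper_pearson"`.
#' @param confidence Confidence level.
#' @param zero_cell_policy Passed to [likelihood_ratios()].
#' @param positive_rule Reference predicate (see [classify_at_threshold()]).
#' @return A `threshold_report`: list of `metric_set` objects, each with
#'   `threshold`, `table`, `prevalence`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `lr_pos`, `lr_neg`, `posttest_pos`, `posttest_neg`.
#' @export
#' @examples
#' rep <- threshold_report(canonical_fixture(), c(2.9, 3.4, 3.5))
#' rep[[1]]$ppv$estimate  # 0.75
threshold_report <- function(cohort, thresholds = c(2.9, 3.4, 3.5),
                             ci_method = c("wilson", "clopper_pearson"),
                             confidence = 0.95,
                             zero_cell_policy = c("exact", "haldane"),
                             positive_rule = function(d) d$pain_category >= 3) {
  if (length(thresholds) == 0) {
    abort_validation("thresholds must be non-empty", "pulpdx_bad_value")
  }
  ci_method <- match.arg(ci_method)
  zero_cell_policy <- match.arg(zero_cell_policy)
  sets <- lapply(thresholds, function(thr) {
    ct <- classify_at_threshold(cohort, thr, positive_rule)
    props <- proportion_metrics(ct, ci_method, confidence)
    lrs <- likelihood_ratios(ct, zero_cell_policy, confidence)
    prev <- (ct$tp + ct$fn) / ct$n
    post <- function(lr) {
      if (is.na(lr) || prev <= 0 || prev >= 1) NA_real_
      else posttest_probability(prev, lr)
    }
    structure(
      list(threshold = thr, table = ct, prevalence = prev,
           sensitivity = props$sensitivity, specificity = props$specificity,
           ppv = props$ppv, npv = props$npv,
           lr_pos = lrs$lr_pos, lr_neg = lrs$lr_neg,
           posttest_pos = post(lrs$lr_pos$estimate),
           posttest_neg = post(lrs$lr_neg$estimate),
           ci_method = ci_method, confidence = confidence,
           zero_cell_policy = zero_cell_policy),
      class = "metric_set"
    )
  })
  structure(sets, class = "threshold_report")
}
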