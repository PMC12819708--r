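#' Imperfect reference standard correction
#'
#' The clinical pain category is a face-valid but imperfect reference:
#' apparent sensitivity and specificity of the biomarker are biased by its
#' misclassification. A Monte Carlo sensitivity analysis draws plausible
#' reference performance (se_r, sp_r) from stated uniform ranges and, for
#' each draw, corrects the apparent accuracy under one of two explicit
#' models:
#'
#' * `"algebraic_inversion"`: assume the index test and the reference err
#'   independently given true disease (conditional independence). Then the
#'   observed joint rates are linear in the latent quantities and the 2x2
#'   system inverts in closed form (the classic misclassification-matrix
#'   correction). Draws whose solution leaves `[0, 1]` are invalid and are
#'   discarded (and counted) or clipped to the boundary.
#' * `"label_perturbation"`: treat the observed labels as noisy, flip each
#'   observed-positive with probability `1 - se_r` and each
#'   observed-negative with probability `1 - sp_r`, and recompute the
#'   index test's accuracy against the perturbed labels.
#'
#' Neither model is privileged: the model identifier is mandatory in all
#' outputs.
#'
#' @name imperfect_reference
NULL

#' Reference-standard assumption for the Monte Carlo correction
#'
#' Defaults are the published plausible ranges for clinical pain
#' assessment: sensitivity 75–90%, specificity 60–80%, 10,000 iterations.
#'
#' @param se_range,sp_range Length-2 vectors `(low, high)` with
#'   `0 < low <= high <= 1`.
#' @param n_iterations Number of Monte Carlo draws (`>= 1`).
#' @param model `"algebraic_inversion"` or `"label_perturbation"`.
#' @param invalid_policy `"discard"` or `"clip"` (algebraic model only).
#' @param seed Integer seed.
#' @return A validated `reference_assumption` list.
#' @export
reference_assumption <- function(se_range = c(0.75, 0.90),
                                 sp_range = c(0.60, 0.80),
                                 n_iterations = 10000,
                                 model = c("algebraic_inversion", "label_perturbation"),
                                 invalid_policy = c("discard", "clip"),
                                 seed = 20250307) {
  model <- match.arg(model)
  invalid_policy <- match.arg(invalid_policy)
  chk <- function(r, what) {
    if (length(r) != 2 || r[1] <= 0 || r[1] > r[2] || r[2] > 1) {
      abort_validation(sprintf("%s must satisfy 0 < low <= high <= 1", what),
                       "pulpdx_bad_config")
    }
  }
  chk(se_range, "se_range")
  chk(sp_range, "sp_range")
  if (n_iterations < 1) abort_validation("n_iterations must be >= 1", "pulpdx_bad_config")
  structure(
    list(se_range = se_range, sp_range = sp_range,
         n_iterations = as.integer(n_iterations), model = model,
         invalid_policy = invalid_policy, seed = as.integer(seed)),
    class = "reference_assumption"
  )
}

#' Draw reference performance pairs
#'
#' Independent uniform draws of `(se_r, sp_r)` on the assumption's ranges;
#' deterministic under the assumption's seed.
#'
#' @param assumption A [reference_assumption()].
#' @param n Number of draws (default: the assumption's `n_iterations`).
#' @return A data frame with columns `se_r`, `sp_r`.
#' @export
sample_reference_performance <- function(assumption, n = assumption$n_iterations) {
  with_seed(assumption$seed, {
    data.frame(
      se_r = stats::runif(n, assumption$se_range[1], assumption$se_range[2]),
      sp_r = stats::runif(n, assumption$sp_range[1], assumption$sp_range[2])
    )
  })
}

#' Forward-compose observed rates under conditional independence
#'
#' Given latent prevalence and true test/reference accuracies, returns the
#' population rates the algebraic inversion sees: `p11 = P(test+, ref+)`,
#' `p10 = P(test+, ref-)` and `q = P(ref+)`. The noiseless inverse of
#' [invert_misclassification()].
#'
#' @param prevalence True disease prevalence in (0, 1).
#' @param se_t,sp_t True index-test sensitivity and specificity.
#' @param se_r,sp_r True reference sensitivity and specificity.
#' @return A list `(p11, p10, q)`.
#' @export
compose_observed_rates <- function(prevalence, se_t, sp_t, se_r, sp_r) {
  p11 <- prevalence * se_t * se_r + (1 - prevalence) * (1 - sp_t) * (1 - sp_r)
  p10 <- prevalence * se_t * (1 - se_r) + (1 - prevalence) * (1 - sp_t) * sp_r
  q <- prevalence * se_r + (1 - prevalence) * (1 - sp_r)
  list(p11 = p11, p10 = p10, q = q)
}

#' Algebraic misclassification inversion
#'
#' Corrects an apparent 2x2 table for assumed reference misclassification
#' under conditional independence. With `q` the observed reference-positive
#' rate, the true prevalence estimate is
#' `pi = (q + sp_r - 1) / (se_r + sp_r - 1)`; the observed joint rates
#' `P(test+, ref+)` and `P(test+, ref-)` are then linear in
#' `(pi * se_t, (1 - pi) * (1 - sp_t))` and the 2x2 system is solved in
#' closed form. Vectorised over `se_r` / `sp_r`.
#'
#' @param ct A [confusion_table()].
#' @param se_r,sp_r Assumed reference sensitivity and specificity
#'   (vectors allowed; must satisfy `se_r + sp_r > 1`).
#' @return A data frame with columns `se_t`, `sp_t`, `prevalence`, `valid`
#'   (`FALSE` when any solution component leaves `[0, 1]`; such rows keep
#'   their raw out-of-range solutions so callers can discard or clip).
#' @export
invert_misclassification <- function(ct, se_r, sp_r) {
  if (any(se_r + sp_r <= 1)) {
    abort_validation("reference must beat chance: se_r + sp_r > 1", "pulpdx_bad_config")
  }
  n <- ct$n
  p11 <- ct$tp / n
  p10 <- ct$fp / n
  q <- (ct$tp + ct$fn) / n
  det <- se_r + sp_r - 1
  prevalence <- (q + sp_r - 1) / det
  a <- (sp_r * p11 - (1 - sp_r) * p10) / det        # pi * se_t
  b <- (se_r * p10 - (1 - se_r) * p11) / det        # (1 - pi) * (1 - sp_t)
  se_t <- a / prevalence
  sp_t <- 1 - b / (1 - prevalence)
  valid <- prevalence > 0 & prevalence < 1 &
    se_t >= 0 & se_t <= 1 & sp_t >= 0 & sp_t <= 1
  valid[is.na(valid)] <- FALSE
  data.frame(se_t = se_t, sp_t = sp_t, prevalence = prevalence, valid = valid)
}

#' Label-perturbation correction
#'
#' Treats the observed reference labels as noisy: flips each
#' observed-positive to negative with probability `1 - se_r` and each
#' observed-negative to positive with probability `1 - sp_r`, then
#' recomputes the index test's Se/Sp against the perturbed labels.
#' Perturbations that leave a single class are redrawn (capped at 1000
#' attempts per draw).
#'
#' @param cohort A validated cohort.
#' @param threshold Index-test positivity threshold (mg/L).
#' @param se_r,sp_r Assumed reference sensitivity and specificity (scalars).
#' @param positive_rule Reference predicate.
#' @return A list `(se_t, sp_t)`: apparent accuracy against one perturbed
#'   labelling. Draws from the caller's RNG stream (seed it via
#'   [monte_carlo_correction()] or `set.seed()`).
#' @export
perturb_labels_correction <- function(cohort, threshold, se_r, sp_r,
                                      positive_rule = function(d) d$pain_category >= 3) {
  ref <- positive_rule(as.data.frame(cohort))
  if (!any(ref) || all(ref)) {
    abort_validation("both reference classes must be present", "pulpdx_single_class")
  }
  test <- cohort$hs_crp >= threshold
  n <- length(ref)
  for (attempt in seq_len(1000)) {
    flip <- stats::runif(n) < ifelse(ref, 1 - se_r, 1 - sp_r)
    lab <- xor(ref, flip)
    if (any(lab) && !all(lab)) {
      return(list(se_t = sum(test & lab) / sum(lab),
                  sp_t = sum(!test & !lab) / sum(!lab)))
    }
  }
  abort_validation("single-class perturbation cap exceeded", "pulpdx_perturbation_cap")
}

#' Monte Carlo correction for an imperfect reference
#'
#' Runs `n_iterations` draws of `(se_r, sp_r)` through the assumption's
#' correction model and summarises the valid corrected draws by median and
#' quartiles (linear-interpolation rule, as in the cohort summaries).
#'
#' @param cohort A validated cohort.
#' @param threshold Index-test positivity threshold (mg/L).
#' @param assumption A [reference_assumption()].
#' @param keep_draws Keep the per-draw data frame (for violin-style
#'   output)?
#' @param positive_rule Reference predicate.
#' @return A `correction_summary` list: `corrected_se` and `corrected_sp`
#'   (each `c(median, q1, q3)`), `n_valid`, `n_invalid`, `model`,
#'   `invalid_policy`, `threshold`, and `draws` when requested (columns
#'   `se_r`, `sp_r`, `se_t`, `sp_t`, `valid`). If every draw is invalid
#'   the summaries are `NA` and the result is flagged `empty`.
#' @export
#' @examples
#' mc <- monte_carlo_correction(canonical_fixture(), 3.4,
#'   reference_assumption(n_iterations = 500, seed = 1))
#' mc$corrected_sp["median"]
monte_carlo_correction <- function(cohort, threshold, assumption,
                                   keep_draws = FALSE,
                                   positive_rule = function(d) d$pain_category >= 3) {
  validate_cohort(cohort)
  perf <- sample_reference_performance(assumption)
  ct <- classify_at_threshold(cohort, threshold, positive_rule)

  if (assumption$model == "algebraic_inversion") {
    sol <- invert_misclassification(ct, perf$se_r, perf$sp_r)
    if (assumption$invalid_policy == "clip") {
      sol$se_t <- clamp(sol$se_t, 0, 1)
      sol$sp_t <- clamp(sol$sp_t, 0, 1)
      used <- rep(TRUE, nrow(sol))
    } else {
      used <- sol$valid
    }
    draws <- data.frame(se_r = perf$se_r, sp_r = perf$sp_r,
                        se_t = sol$se_t, sp_t = sol$sp_t, valid = sol$valid)
  } else {
    out <- with_seed(derive_seed(assumption$seed, 97L), {
      lapply(seq_len(assumption$n_iterations), function(i) {
        perturb_labels_correction(cohort, threshold,
                                  perf$se_r[i], perf$sp_r[i], positive_rule)
      })
    })
    draws <- data.frame(se_r = perf$se_r, sp_r = perf$sp_r,
                        se_t = vapply(out, `[[`, numeric(1), "se_t"),
                        sp_t = vapply(out, `[[`, numeric(1), "sp_t"),
                        valid = TRUE)
    used <- draws$valid
  }

  summ <- function(v) {
    if (!any(used)) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
    q <- stats::quantile(v[used], c(0.5, 0.25, 0.75), type = 7, names = FALSE)
    c(median = q[1], q1 = q[2], q3 = q[3])
  }
  structure(
    list(corrected_se = summ(draws$se_t),
         corrected_sp = summ(draws$sp_t),
         n_valid = sum(draws$valid),
         n_invalid = sum(!draws$valid),
         empty = !any(used),
         model = assumption$model,
         invalid_policy = assumption$invalid_policy,
         threshold = threshold,
         n_iterations = assumption$n_iterations,
         seed = assumption$seed,
         draws = if (keep_draws) draws else NULL),
    class = "correction_summary"
  )
}
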