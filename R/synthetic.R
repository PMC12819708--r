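#' Synthetic cohort generator
#'
#' Emulates the statistical structure of the pilot cohort: an ordinal pain
#' category drawn from fixed probabilities, a right-skewed log-normal
#' hs-CRP distribution whose log-location increases with category (a
#' monotone dose-response by construction), a category-dependent chance of
#' an undetectable value, multiplicative assay noise at a stated
#' coefficient of variation, left-censoring at the 0.5 mg/L detection limit
#' and clipping at the 200 mg/L assay ceiling, and a VAS score that is a
#' monotone map of category plus truncated Gaussian noise.
#'
#' @name synthetic
NULL

#' Generator configuration
#'
#' Defaults reflect the published cohort: category mix 0/2/5/6 out of 13
#' (none/mild/moderate/severe), undetectable fractions falling with
#' severity (both mild values and two of five moderate values were
#' undetectable; no severe value was), log-scale locations rising with
#' severity so that severe values centre near 5 mg/L with a right tail
#' reaching the published 18 mg/L maximum, assay CV 0.10 (the platform's
#' stated "<10%"), and detection limit 0.5 mg/L.
#'
#' @param n Number of subjects.
#' @param category_probs Probabilities of pain categories 0:3; must sum to 1.
#' @param location_by_category Log-scale means (log mg/L) per category;
#'   must be non-decreasing.
#' @param sigma_log Log-scale SD (common to categories), `>= 0`.
#' @param undetectable_prob_by_category Probability of an undetectable
#'   value per category; must be non-increasing.
#' @param lod Detection limit (mg/L); measured values below it are stored
#'   as 0.0 with the censoring flag.
#' @param assay_cv Coefficient of variation of the multiplicative
#'   measurement noise (proportion).
#' @param vas_noise_sd SD (cm) of the Gaussian noise added to the
#'   category-to-VAS map `2.5 + 2 * category`, clamped to `[0, 10]`.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n = 13,
                             category_probs = c(0, 2, 5, 6) / 13,
                             location_by_category = log(c(0.5, 1.2, 2.5, 5.0)),
                             sigma_log = 0.8,
                             undetectable_prob_by_category = c(0.9, 0.9, 0.4, 0.0),
                             lod = 0.5,
                             assay_cv = 0.10,
                             vas_noise_sd = 1.0,
                             seed = 20250307) {
  cfg <- list(n = as.integer(n), category_probs = category_probs,
              location_by_category = location_by_category,
              sigma_log = sigma_log,
              undetectable_prob_by_category = undetectable_prob_by_category,
              lod = lod, assay_cv = assay_cv, vas_noise_sd = vas_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n < 1) abort_validation("n must be >= 1", "pulpdx_bad_config")
  if (length(cfg$category_probs) != 4 || any(cfg$category_probs < 0) ||
      abs(sum(cfg$category_probs) - 1) > 1e-8) {
    abort_validation("category_probs must be a 4-vector of probabilities summing to 1",
                     "pulpdx_bad_config")
  }
  if (length(cfg$location_by_category) != 4 ||
      is.unsorted(cfg$location_by_category)) {
    abort_validation("location_by_category must be non-decreasing (monotone dose-response)",
                     "pulpdx_bad_config")
  }
  if (cfg$sigma_log < 0) abort_validation("sigma_log must be >= 0", "pulpdx_bad_config")
  u <- cfg$undetectable_prob_by_category
  if (length(u) != 4 || any(u < 0 | u > 1) || is.unsorted(rev(u))) {
    abort_validation("undetectable_prob_by_category must be non-increasing probabilities",
                     "pulpdx_bad_config")
  }
  if (cfg$lod < 0 || cfg$assay_cv < 0 || cfg$vas_noise_sd < 0) {
    abort_validation("lod, assay_cv and vas_noise_sd must be non-negative",
                     "pulpdx_bad_config")
  }
  invisible(cfg)
}

#' Generate a synthetic cohort
#'
#' Per subject: draw the pain category; with the category's undetectable
#' probability emit `hs_crp = 0.0` with the censoring flag; otherwise draw
#' the true concentration from the category's log-normal, apply
#' multiplicative log-normal measurement noise with mean 1 and CV
#' `assay_cv`, left-censor below `lod` (stored 0.0 + flag) and clip at 200
#' mg/L (over-range flag). VAS is `2.5 + 2 * category` plus Gaussian noise,
#' clamped to `[0, 10]`. Identical seeds give identical cohorts.
#'
#' @param config A [synthetic_config()].
#' @return A validated cohort with provenance `"synthetic"`.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n = 13, seed = 7))
#' summarize_cohort(cohort)$crp_median
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  with_seed(config$seed, {
    n <- config$n
    category <- sample(0:3, n, replace = TRUE, prob = config$category_probs)
    undetectable <- stats::runif(n) < config$undetectable_prob_by_category[category + 1]
    true_conc <- exp(stats::rnorm(n, config$location_by_category[category + 1],
                                  config$sigma_log))
    # multiplicative log-normal noise with E[noise] = 1, CV = assay_cv
    s <- sqrt(log(1 + config$assay_cv^2))
    measured <- true_conc * exp(stats::rnorm(n, -s^2 / 2, s))
    vas <- clamp(2.5 + 2 * category + stats::rnorm(n, 0, config$vas_noise_sd), 0, 10)

    hs_crp <- measured
    hs_crp[undetectable] <- 0
    below <- undetectable | hs_crp < config$lod
    hs_crp[below] <- 0
    over <- hs_crp > ASSAY_UPPER_LIMIT
    hs_crp[over] <- ASSAY_UPPER_LIMIT

    new_cohort(
      patient_id = sprintf("S%04d", seq_len(n)),
      hs_crp = hs_crp,
      below_lod = below,
      vas = vas,
      pain_category = category,
      tooth_type = NA_character_,
      over_range = over,
      provenance = "synthetic"
    )
  })
}
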