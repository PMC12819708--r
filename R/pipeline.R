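#' Full analysis pipeline and report rendering
#'
#' One call runs the complete diagnostic-accuracy analysis on a cohort —
#' descriptive summary, Spearman correlations of hs-CRP with the ordinal
#' pain category and with VAS (permutation p-values, pairs-bootstrap CIs),
#' empirical ROC with bootstrap AUC CI and Youden-optimal threshold, the
#' multi-threshold metric table, the Monte Carlo imperfect-reference
#' correction, and the Shapiro-Wilk normality assessment — with every
#' stochastic stage seeded deterministically from one master seed so the
#' report replays exactly.
#'
#' @name cli_report
NULL

REPORT_SCHEMA_VERSION <- "1.0"

#' Pipeline configuration
#'
#' @param input Path to a cohort CSV, or `NULL` to analyse `cohort`.
#' @param cohort A cohort object (ignored when `input` is given; default
#'   [canonical_fixture()]).
#' @param thresholds Thresholds (mg/L) for the metric table.
#' @param ci_method Binomial interval method for the table.
#' @param confidence Confidence level used throughout.
#' @param bootstrap_b Bootstrap resamples for rho and AUC intervals.
#' @param assumption A [reference_assumption()]; its seed is overridden by
#'   a seed derived from `seed`.
#' @param mc_threshold Threshold (mg/L) for the imperfect-reference
#'   correction.
#' @param seed Master seed; all module seeds derive from it.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(input = NULL, cohort = canonical_fixture(),
                            thresholds = c(2.9, 3.4, 3.5),
                            ci_method = "wilson", confidence = 0.95,
                            bootstrap_b = 10000,
                            assumption = reference_assumption(),
                            mc_threshold = 3.4,
                            seed = 20250307) {
  structure(
    list(input = input, cohort = cohort, thresholds = thresholds,
         ci_method = ci_method, confidence = confidence,
         bootstrap_b = as.integer(bootstrap_b), assumption = assumption,
         mc_threshold = mc_threshold, seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Run the full analysis
#'
#' @param config An [analysis_config()].
#' @return An `analysis_report` list with components `settings`,
#'   `cohort_summary`, `correlation` (vs category and vs VAS),
#'   `normality`, `roc` (curve, AUC, bootstrap CI, Youden point),
#'   `threshold_metrics`, and `correction`.
#' @export
#' @examples
#' rep <- run_pipeline(analysis_config(
#'   bootstrap_b = 200,
#'   assumption = reference_assumption(n_iterations = 200)))
#' rep$threshold_metrics[[1]]$ppv$estimate
run_pipeline <- function(config) {
  cohort <- if (!is.null(config$input)) read_cohort(config$input) else config$cohort
  validate_cohort(cohort)
  seed_rho_cat <- derive_seed(config$seed, 1L)
  seed_rho_vas <- derive_seed(config$seed, 2L)
  seed_auc <- derive_seed(config$seed, 3L)
  seed_mc <- derive_seed(config$seed, 4L)

  corr_block <- function(yvar, seed) {
    y <- cohort[[yvar]]
    rho <- suppressWarnings(spearman_rho(cohort$hs_crp, y))
    if (is.na(rho)) {
      return(list(variable = yvar, rho = NA_real_, p_value = NA_real_,
                  p_method = "permutation", ci = c(lower = NA_real_, upper = NA_real_),
                  b = config$bootstrap_b, seed = seed))
    }
    list(
      variable = yvar,
      rho = rho,
      p_value = correlation_pvalue(cohort$hs_crp, y, "permutation",
                                   b = config$bootstrap_b, seed = seed),
      p_method = "permutation",
      ci = bootstrap_ci_statistic(cohort$hs_crp, y, spearman_rho,
                                  b = config$bootstrap_b,
                                  confidence = config$confidence, seed = seed),
      b = config$bootstrap_b,
      seed = seed
    )
  }

  roc <- empirical_roc(cohort)
  assumption <- config$assumption
  assumption$seed <- seed_mc

  structure(
    list(
      schema_version = REPORT_SCHEMA_VERSION,
      settings = list(
        thresholds = config$thresholds, ci_method = config$ci_method,
        confidence = config$confidence, bootstrap_b = config$bootstrap_b,
        mc_threshold = config$mc_threshold, seed = config$seed,
        mc_model = assumption$model, mc_iterations = assumption$n_iterations,
        mc_se_range = assumption$se_range, mc_sp_range = assumption$sp_range,
        mc_invalid_policy = assumption$invalid_policy,
        provenance = attr(cohort, "provenance")
      ),
      cohort_summary = summarize_cohort(cohort),
      correlation = list(category = corr_block("pain_category", seed_rho_cat),
                         vas = corr_block("vas", seed_rho_vas)),
      normality = shapiro_wilk(cohort$hs_crp),
      roc = list(
        curve = roc,
        auc = roc$auc,
        auc_ci = auc_bootstrap_ci(cohort, b = config$bootstrap_b,
                                  confidence = config$confidence, seed = seed_auc),
        youden = youden_optimal(roc)
      ),
      threshold_metrics = threshold_report(cohort, config$thresholds,
                                           config$ci_method, config$confidence),
      correction = monte_carlo_correction(cohort, config$mc_threshold, assumption)
    ),
    class = "analysis_report"
  )
}

#' Render an analysis report
#'
#' `"json"` gives a lossless machine-readable serialisation (full
#' precision; undefined and infinite quantities as explicit
#' `{value: null, reason: ...}` objects). `"text"` gives a human-readable
#' summary whose metric table follows the column order
#' `Threshold (mg/L) | Sensitivity (95% CI) | Specificity (95% CI) |
#' LR+ (95% CI) | LR- (95% CI) | PPV | NPV`, percentages rounded half-up
#' to whole percent and undefined entries shown as `(–)`.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param format `"json"` or `"text"`.
#' @return A character scalar (the serialised report).
#' @export
render_report <- function(report, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(report_to_list(report),
                                         auto_unbox = TRUE, digits = NA,
                                         null = "null", na = "null")))
  }
  render_text_report(report)
}

# Plain-list view used for JSON; replaces non-finite numbers by explicit
# null-with-reason objects so the serialisation is lossless and stable.
report_to_list <- function(report) {
  num <- function(x, reason = "undefined") {
    if (length(x) == 1 && (is.na(x) || is.infinite(x))) {
      list(value = NULL,
           reason = if (length(x) == 1 && !is.na(x) && is.infinite(x)) "infinite" else reason)
    } else {
      unname(x)
    }
  }
  ci_list <- function(p) list(estimate = num(p$estimate), lower = num(p$lower),
                              upper = num(p$upper), method = p$method,
                              confidence = p$confidence)
  lr_list <- function(l) list(estimate = num(l$estimate), lower = num(l$lower),
                              upper = num(l$upper), finite = l$finite)
  ms_list <- function(ms) list(
    threshold = ms$threshold,
    table = list(tp = ms$table$tp, fp = ms$table$fp,
                 fn = ms$table$fn, tn = ms$table$tn),
    prevalence = ms$prevalence,
    sensitivity = ci_list(ms$sensitivity), specificity = ci_list(ms$specificity),
    ppv = ci_list(ms$ppv), npv = ci_list(ms$npv),
    lr_pos = lr_list(ms$lr_pos), lr_neg = lr_list(ms$lr_neg),
    posttest_pos = num(ms$posttest_pos), posttest_neg = num(ms$posttest_neg),
    rounded_percent = list(
      sensitivity = pct_or_null(ms$sensitivity$estimate),
      specificity = pct_or_null(ms$specificity$estimate),
      ppv = pct_or_null(ms$ppv$estimate),
      npv = pct_or_null(ms$npv$estimate)
    )
  )
  cs <- report$cohort_summary
  corr_list <- function(cb) list(
    variable = cb$variable, rho = num(cb$rho), p_value = num(cb$p_value),
    p_method = cb$p_method,
    ci = list(lower = num(cb$ci[["lower"]]), upper = num(cb$ci[["upper"]])),
    b = cb$b, seed = cb$seed
  )
  corr <- report$correction
  list(
    schema_version = report$schema_version,
    settings = report$settings,
    cohort_summary = list(
      n = cs$n, category_counts = cs$category_counts,
      crp_median = cs$crp_median, crp_q1 = cs$crp_q1, crp_q3 = cs$crp_q3,
      crp_max = cs$crp_max, vas_mean = cs$vas_mean, vas_sd = num(cs$vas_sd),
      quartile_type = cs$quartile_type
    ),
    correlation = list(category = corr_list(report$correlation$category),
                       vas = corr_list(report$correlation$vas)),
    normality = list(w_statistic = num(report$normality$w_statistic),
                     p_value = num(report$normality$p_value),
                     n = report$normality$n),
    roc = list(
      auc = report$roc$auc,
      auc_ci = list(lower = report$roc$auc_ci[["lower"]],
                    upper = report$roc$auc_ci[["upper"]]),
      youden = report$roc$youden,
      n_pos = report$roc$curve$n_pos, n_neg = report$roc$curve$n_neg,
      operating_points = lapply(seq_len(nrow(report$roc$curve$operating_points)),
        function(i) {
          op <- report$roc$curve$operating_points[i, ]
          list(threshold = if (is.infinite(op$threshold)) "Inf" else op$threshold,
               fpr = op$fpr, tpr = op$tpr)
        })
    ),
    threshold_metrics = lapply(report$threshold_metrics, ms_list),
    correction = list(
      model = corr$model, invalid_policy = corr$invalid_policy,
      threshold = corr$threshold, n_iterations = corr$n_iterations,
      corrected_se = list(median = num(corr$corrected_se[["median"]]),
                          q1 = num(corr$corrected_se[["q1"]]),
                          q3 = num(corr$corrected_se[["q3"]])),
      corrected_sp = list(median = num(corr$corrected_sp[["median"]]),
                          q1 = num(corr$corrected_sp[["q1"]]),
                          q3 = num(corr$corrected_sp[["q3"]])),
      n_valid = corr$n_valid, n_invalid = corr$n_invalid
    )
  )
}

pct_or_null <- function(x) if (is.na(x)) NULL else round_half_up(100 * x)

fmt_pct_ci <- function(p) {
  if (is.na(p$estimate)) return("(–)")
  sprintf("%d%% (%d–%d)", round_half_up(100 * p$estimate),
          round_half_up(100 * p$lower), round_half_up(100 * p$upper))
}

fmt_lr <- function(l) {
  if (is.na(l$estimate)) return("(–)")
  if (is.infinite(l$estimate)) return("∞ (–)")
  ci <- if (is.na(l$lower)) "(–)" else sprintf("(%.2f–%.2f)", l$lower, l$upper)
  sprintf("%.2f %s", l$estimate, ci)
}

fmt_pct <- function(x) if (is.na(x)) "(–)" else sprintf("%d%%", round_half_up(100 * x))

render_text_report <- function(report) {
  cs <- report$cohort_summary
  header <- c("Threshold (mg/L)", "Sensitivity (95% CI)", "Specificity (95% CI)",
              "LR+ (95% CI)", "LR− (95% CI)", "PPV", "NPV")
  rows <- lapply(report$threshold_metrics, function(ms) {
    c(sprintf("%.1f", ms$threshold),
      fmt_pct_ci(ms$sensitivity), fmt_pct_ci(ms$specificity),
      fmt_lr(ms$lr_pos), fmt_lr(ms$lr_neg),
      fmt_pct(ms$ppv$estimate), fmt_pct(ms$npv$estimate))
  })
  tab <- rbind(header, do.call(rbind, rows))
  widths <- apply(nchar(tab, type = "width"), 2, max)
  fmt_row <- function(r) {
    paste(mapply(function(cell, w) {
      pad <- w - nchar(cell, type = "width")
      paste0(cell, strrep(" ", pad))
    }, r, widths), collapse = "  ")
  }
  lines <- c(
    "Pulpal-blood hs-CRP diagnostic accuracy report",
    sprintf("Cohort: n = %d (mild %d, moderate %d, severe %d); hs-CRP median %.2f mg/L (IQR %.2f–%.2f), max %.1f",
            cs$n, cs$category_counts[2], cs$category_counts[3], cs$category_counts[4],
            cs$crp_median, cs$crp_q1, cs$crp_q3, cs$crp_max),
    sprintf("Spearman rho vs pain category: %.3f (p = %.4g, 95%% CI %.2f–%.2f)",
            report$correlation$category$rho, report$correlation$category$p_value,
            report$correlation$category$ci[["lower"]],
            report$correlation$category$ci[["upper"]]),
    sprintf("Spearman rho vs VAS: %.3f (p = %.4g)",
            report$correlation$vas$rho, report$correlation$vas$p_value),
    sprintf("ROC AUC: %.3f (95%% CI %.3f–%.3f); Youden-optimal threshold %.2f mg/L (J = %.3f)",
            report$roc$auc, report$roc$auc_ci[["lower"]], report$roc$auc_ci[["upper"]],
            report$roc$youden$threshold, report$roc$youden$j),
    sprintf("Shapiro–Wilk: W = %.3f, p = %.4g", report$normality$w_statistic,
            report$normality$p_value),
    "",
    vapply(seq_len(nrow(tab)), function(i) fmt_row(tab[i, ]), character(1)),
    "",
    sprintf("Imperfect-reference Monte Carlo (%s, %d iterations, threshold %.1f mg/L):",
            report$correction$model, report$correction$n_iterations,
            report$correction$threshold),
    sprintf("  corrected sensitivity median %s (IQR %s–%s); specificity median %s (IQR %s–%s); invalid draws: %d",
            fmt_pct(report$correction$corrected_se[["median"]]),
            fmt_pct(report$correction$corrected_se[["q1"]]),
            fmt_pct(report$correction$corrected_se[["q3"]]),
            fmt_pct(report$correction$corrected_sp[["median"]]),
            fmt_pct(report$correction$corrected_sp[["q1"]]),
            fmt_pct(report$correction$corrected_sp[["q3"]]),
            report$correction$n_invalid)
  )
  paste(lines, collapse = "\n")
}
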