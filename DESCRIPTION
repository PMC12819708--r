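Package: pulpdx
Title: Diagnostic Accuracy Analysis of a Pulpal-Blood hs-CRP Biomarker
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Threshold-based diagnostic accuracy analysis of a point-of-care
    pulpal-blood high-sensitivity C-reactive protein (hs-CRP) biomarker read
    against an ordinal clinical pain reference: 2x2 confusion tables with
    Wilson and Clopper-Pearson binomial intervals, likelihood ratios with
    log-method confidence intervals, Bayesian post-test probabilities,
    tie-aware empirical ROC curves and Mann-Whitney AUC with stratified
    percentile-bootstrap intervals, Youden-optimal thresholds, mid-rank
    Spearman correlation with permutation p-values and pairs-bootstrap
    intervals, Shapiro-Wilk normality summaries with Q-Q and histogram
    series, and Monte Carlo correction of apparent accuracy for an imperfect
    clinical reference standard under two explicit correction models.
    Includes a detection-limit-censored log-normal synthetic cohort
    generator and a canonical 13-patient fixture.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
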