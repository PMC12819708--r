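# pulpdx

Diagnostic-accuracy analysis of a point-of-care pulpal-blood
high-sensitivity C-reactive protein (hs-CRP) biomarker for identifying the
severe inflammatory phenotype of irreversible pulpitis, read against an
ordinal clinical pain reference.

The package is aimed at biostatisticians and clinical researchers working
with small diagnostic pilot cohorts where (a) the biomarker is
detection-limit censored, (b) the reference standard is an ordinal,
imperfect clinical judgement, and (c) every number must be reproducible
from a seed.

## What it computes

For a cohort of patients with an hs-CRP concentration *x* (mg/L; values
below the 0.5 mg/L detection limit recorded as 0), a VAS pain score and an
ordinal pain category (0–3), with the reference "severe" defined as
category ≥ 3 and test positivity as *x* ≥ *c*:

* **2×2 accuracy** — Se, Sp, PPV, NPV with Wilson score or
  Clopper–Pearson exact intervals; likelihood ratios
  LR+ = Se/(1−Sp), LR− = (1−Se)/Sp with log-method CIs
  (SE = √(1/tp − 1/(tp+fn) + 1/fp − 1/(fp+tn)) for LR+); Bayesian
  post-test probability *p·LR / (p·LR + 1 − p)*, which at the sample
  prevalence equals the PPV exactly.
* **ROC** — empirical curve over realised thresholds, tie-aware
  Mann–Whitney AUC (= trapezoidal area exactly), stratified
  percentile-bootstrap AUC interval, Youden-optimal threshold
  (max J = Se + Sp − 1, ties toward specificity).
* **Association** — Spearman ρ as Pearson correlation of mid-ranks,
  permutation p-values with plus-one correction, pairs-bootstrap
  percentile CIs; Shapiro–Wilk normality with Q-Q and histogram series.
* **Imperfect-reference correction** — Monte Carlo draws of reference
  (se_r, sp_r) from uniform plausible ranges, corrected through either an
  algebraic misclassification inversion (conditional independence;
  closed-form 2×2 solve with π = (q + sp_r − 1)/(se_r + sp_r − 1);
  out-of-range draws counted and discarded or clipped) or a
  label-perturbation model (flip observed labels at the assumed error
  rates and recompute).
* **Synthetic cohorts** — a seeded generator of detection-limit-censored,
  category-linked log-normal cohorts, plus a canonical 13-patient fixture
  reconstructed from the published classification constraints.

## Worked example

```r
library(pulpdx)

fx <- canonical_fixture()            # 13 patients: 2 mild, 5 moderate, 6 severe
rep <- threshold_report(fx, c(2.9, 3.4, 3.5), ci_method = "wilson")
m <- rep[[1]]                        # threshold 2.9 mg/L
c(se = m$sensitivity$estimate, sp = m$specificity$estimate,
  lr_pos = m$lr_pos$estimate, ppv = m$ppv$estimate, npv = m$npv$estimate)
#>        se        sp    lr_pos       ppv       npv
#> 1.0000000 0.7142857 3.5000000 0.7500000 1.0000000

posttest_probability(6/13, rep[[2]]$lr_pos$estimate)   # 3.4 mg/L, LR+ = 7
#> [1] 0.8571429

empirical_roc(fx)$auc
#> [1] 0.9047619
youden_optimal(empirical_roc(fx))
#> $threshold 3.45   $j 0.857...
```

At 2.9 mg/L the marker finds every severe case (Se 100%) while 5 of 7
non-severe patients test negative (Sp 71%); a positive result at
3.4 mg/L raises the probability of severe pain from the 46% pretest
prevalence to 86%. The full pipeline (`run_pipeline()` /
`render_report()`) adds Spearman correlations, the bootstrap AUC
interval, the Shapiro–Wilk assessment and the imperfect-reference
Monte Carlo, all driven by one master seed.

The numbered scripts under `analysis/` run the complete study analysis
and write tables to `results/`:

```sh
Rscript analysis/01_cohort.R
Rscript analysis/02_threshold_metrics.R
Rscript analysis/03_roc_correlation.R
Rscript analysis/04_reference_correction.R
Rscript analysis/05_full_report.R
```

Note the cohort is a constrained reconstruction — its classification
pattern (and hence all 2×2 arithmetic) is exact, but rank statistics on
it are qualitative analogues of the originally reported values; see the
methods vignette (`vignettes/pulpal-crp-accuracy.Rmd`) for why the two
cannot coincide.

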