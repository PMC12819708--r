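test_that("threshold classification matches hand counts and conserves cells", {
  fx <- canonical_fixture()
  cases <- list(
    list(thr = 2.9, cells = c(6, 2, 0, 5)),
    list(thr = 3.4, cells = c(6, 1, 0, 6)),
    list(thr = 3.5, cells = c(5, 1, 1, 6)),
    list(thr = 0, cells = c(6, 7, 0, 0))     # all test-positive
  )
  for (cs in cases) {
    ct <- classify_at_threshold(fx, cs$thr)
    expect_equal(c(ct$tp, ct$fp, ct$fn, ct$tn), cs$cells,
                 info = sprintf("threshold %.1f", cs$thr))
    expect_equal(ct$n, 13)
  }

  # monotone sweep on random cohorts: tp and fp never increase with threshold
  for (seed in 1:10) {
    co <- two_class_cohort(seed)
    thr <- sort(unique(c(0, co$hs_crp, max(co$hs_crp) + 1)))
    tabs <- lapply(thr, function(t) classify_at_threshold(co, t))
    tp <- vapply(tabs, `[[`, numeric(1), "tp")
    fp <- vapply(tabs, `[[`, numeric(1), "fp")
    expect_true(all(diff(tp) <= 0) && all(diff(fp) <= 0))
    expect_true(all(vapply(tabs, `[[`, numeric(1), "n") == nrow(co)))
  }

  # single-class reference flags the table instead of erroring
  co <- canonical_fixture()
  ct <- classify_at_threshold(co, 2.9, positive_rule = function(d) d$pain_category >= 0)
  expect_true(ct$degenerate)
})

test_that("proportion estimates and both interval methods match closed forms", {
  ct <- confusion_table(6, 2, 0, 5)
  m <- proportion_metrics(ct, "wilson")
  expect_equal(m$sensitivity$estimate, 1.0)
  expect_equal(m$specificity$estimate, 5 / 7, tolerance = 1e-12)
  expect_equal(m$ppv$estimate, 0.75)
  expect_equal(m$npv$estimate, 1.0)

  ct35 <- confusion_table(5, 1, 1, 6)
  m35 <- proportion_metrics(ct35)
  expect_equal(m35$sensitivity$estimate, 5 / 6, tolerance = 1e-12)
  expect_equal(m35$ppv$estimate, 5 / 6, tolerance = 1e-12)

  # frozen closed-form values
  w <- wilson_interval(6, 6, 0.95)
  expect_equal(w$lower, 6 / (6 + qnorm(0.975)^2), tolerance = 1e-12)
  expect_equal(w$lower, 0.6097, tolerance = 1e-4)
  expect_equal(w$upper, 1.0)
  w57 <- wilson_interval(5, 7, 0.95)
  expect_equal(c(w57$lower, w57$upper), c(0.3589, 0.9178), tolerance = 1e-4)

  cp <- clopper_pearson_interval(6, 6, 0.95)
  expect_equal(cp$lower, 0.025^(1 / 6), tolerance = 1e-12)
  expect_equal(cp$lower, 0.5407, tolerance = 1e-4)
  expect_equal(cp$upper, 1.0)
  cp57 <- clopper_pearson_interval(5, 7, 0.95)
  expect_equal(c(cp57$lower, cp57$upper), c(0.2904, 0.9633), tolerance = 1e-4)
  # exact interval inverts the binomial tails
  expect_equal(pbinom(5 - 1, 7, cp57$lower, lower.tail = FALSE), 0.025, tolerance = 1e-8)
  expect_equal(pbinom(5, 7, cp57$upper), 0.025, tolerance = 1e-8)

  # complement symmetry: interval(k, n) mirrors interval(n - k, n)
  for (k in 0:6) {
    w1 <- wilson_interval(k, 6); w2 <- wilson_interval(6 - k, 6)
    expect_equal(w1$lower, 1 - w2$upper, tolerance = 1e-12)
    c1 <- clopper_pearson_interval(k, 6); c2 <- clopper_pearson_interval(6 - k, 6)
    expect_equal(c1$lower, 1 - c2$upper, tolerance = 1e-10)
  }

  # both methods contain the point estimate; widths shrink with n
  for (k_n in list(c(3, 8), c(10, 12), c(0, 5))) {
    for (f in list(wilson_interval, clopper_pearson_interval)) {
      ci <- f(k_n[1], k_n[2])
      expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
      big <- f(k_n[1] * 10, k_n[2] * 10)
      expect_lt(big$upper - big$lower, ci$upper - ci$lower)
    }
  }

  # zero denominator: that proportion undefined, others unaffected
  m0 <- proportion_metrics(confusion_table(0, 0, 0, 10))
  expect_true(is.na(m0$sensitivity$estimate))
  expect_equal(m0$specificity$estimate, 1.0)
  expect_true(is.na(m0$ppv$estimate))
})

test_that("likelihood ratios follow the log-method under both zero-cell policies", {
  ct <- confusion_table(6, 2, 0, 5)
  lr <- likelihood_ratios(ct, "exact")
  expect_equal(lr$lr_pos$estimate, 3.5, tolerance = 1e-12)
  # SE = sqrt(1/6 - 1/6 + 1/2 - 1/7)
  se <- sqrt(1 / 2 - 1 / 7)
  expect_equal(lr$lr_pos$lower, 3.5 * exp(-qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(c(lr$lr_pos$lower, lr$lr_pos$upper), c(1.0849, 11.2917), tolerance = 1e-4)
  # zero false negatives: LR- exactly 0 with undefined CI
  expect_identical(lr$lr_neg$estimate, 0)
  expect_true(is.na(lr$lr_neg$lower))

  lr34 <- likelihood_ratios(confusion_table(6, 1, 0, 6), "exact")
  expect_equal(lr34$lr_pos$estimate, 7, tolerance = 1e-12)
  expect_identical(lr34$lr_neg$estimate, 0)

  # zero false positives: infinite LR+ flagged, not an exception
  lrinf <- likelihood_ratios(confusion_table(5, 0, 1, 6), "exact")
  expect_true(is.infinite(lrinf$lr_pos$estimate) && !lrinf$lr_pos$finite)

  # all test-negative: LR+ is 0/0, undefined rather than infinite
  lr00 <- likelihood_ratios(confusion_table(0, 0, 6, 7), "exact")
  expect_true(is.na(lr00$lr_pos$estimate))

  # haldane policy always yields finite LRs with finite CIs
  lh <- likelihood_ratios(confusion_table(5, 0, 1, 6), "haldane")
  expect_true(is.finite(lh$lr_pos$estimate) && is.finite(lh$lr_pos$lower))
  expect_equal(lh$lr_pos$estimate, (5.5 / 7) / (0.5 / 7), tolerance = 1e-12)
})

test_that("post-test probability is the odds-form Bayes update", {
  expect_equal(posttest_probability(6 / 13, 7), 6 / 7, tolerance = 1e-12)
  expect_equal(round(100 * posttest_probability(6 / 13, 7)), 86)
  expect_equal(posttest_probability(0.3, 1), 0.3, tolerance = 1e-12)
  expect_equal(posttest_probability(6 / 13, 0), 0)
  expect_equal(posttest_probability(0.2, Inf), 1)
  expect_error(posttest_probability(0, 2), class = "pulpdx_bad_value")
  expect_error(posttest_probability(1, 2), class = "pulpdx_bad_value")

  # Bayes identities on every finite-LR table from random cohorts:
  # posttest(prevalence, LR+) == PPV and posttest(prevalence, LR-) == 1 - NPV
  for (seed in 1:15) {
    co <- two_class_cohort(seed)
    for (thr in unique(co$hs_crp)) {
      ct <- classify_at_threshold(co, thr)
      if (ct$tp + ct$fp == 0 || ct$tn + ct$fn == 0) next
      lrs <- likelihood_ratios(ct, "exact")
      prev <- (ct$tp + ct$fn) / ct$n
      if (prev <= 0 || prev >= 1) next
      m <- proportion_metrics(ct)
      if (is.finite(lrs$lr_pos$estimate) && !is.na(lrs$lr_pos$estimate)) {
        expect_equal(posttest_probability(prev, lrs$lr_pos$estimate),
                     m$ppv$estimate, tolerance = 1e-12)
      }
      if (is.finite(lrs$lr_neg$estimate) && !is.na(lrs$lr_neg$estimate)) {
        expect_equal(posttest_probability(prev, lrs$lr_neg$estimate),
                     1 - m$npv$estimate, tolerance = 1e-12)
      }
    }
  }
})

test_that("vectorized metrics agree with a naive per-record oracle", {
  for (seed in c(2, 13, 31)) {
    co <- two_class_cohort(seed)
    thr <- stats::median(co$hs_crp)
    tp <- fp <- fn <- tn <- 0
    for (i in seq_len(nrow(co))) {       # explicit per-record loop
      test_pos <- co$hs_crp[i] >= thr
      ref_pos <- co$pain_category[i] >= 3
      if (test_pos && ref_pos) tp <- tp + 1
      else if (test_pos) fp <- fp + 1
      else if (ref_pos) fn <- fn + 1
      else tn <- tn + 1
    }
    ct <- classify_at_threshold(co, thr)
    expect_equal(c(ct$tp, ct$fp, ct$fn, ct$tn), c(tp, fp, fn, tn))
    m <- proportion_metrics(ct)
    expect_equal(m$sensitivity$estimate, tp / (tp + fn))
    expect_equal(m$specificity$estimate, tn / (tn + fp))
    lr <- likelihood_ratios(ct)
    if (fp > 0) {
      expect_equal(lr$lr_pos$estimate,
                   (tp / (tp + fn)) / (fp / (fp + tn)), tolerance = 1e-12)
    }
  }
})

test_that("multi-threshold report mirrors the published table structure", {
  fx <- canonical_fixture()
  rep <- threshold_report(fx, c(2.9, 3.4, 3.5))
  expect_length(rep, 3)
  expect_equal(vapply(rep, `[[`, numeric(1), "threshold"), c(2.9, 3.4, 3.5))
  expect_equal(rep[[1]]$ppv$estimate, 0.75)
  expect_equal(rep[[1]]$npv$estimate, 1.0)
  expect_equal(rep[[2]]$posttest_pos, 6 / 7, tolerance = 1e-12)

  r0 <- threshold_report(fx, 0.0)[[1]]
  expect_equal(r0$sensitivity$estimate, 1.0)
  expect_equal(r0$specificity$estimate, 0.0)

  rbig <- threshold_report(fx, 1000.0)[[1]]
  expect_equal(rbig$sensitivity$estimate, 0.0)
  expect_true(is.na(rbig$lr_pos$estimate))     # 0/0 undefined flag
  expect_true(is.na(rbig$ppv$estimate))        # no test-positives

  expect_error(threshold_report(fx, numeric(0)), class = "pulpdx_bad_value")
})
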