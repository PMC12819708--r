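test_that("reference performance draws are uniform on the stated ranges", {
  a <- reference_assumption(se_range = c(0.8, 0.8), sp_range = c(0.7, 0.7),
                            n_iterations = 200, seed = 3)
  d <- sample_reference_performance(a)
  expect_true(all(d$se_r == 0.8) && all(d$sp_r == 0.7))

  a <- reference_assumption(n_iterations = 10000, seed = 12)
  d <- sample_reference_performance(a)
  expect_true(all(d$se_r >= 0.75 & d$se_r <= 0.90))
  expect_true(all(d$sp_r >= 0.60 & d$sp_r <= 0.80))
  expect_lt(abs(mean(d$se_r) - 0.825), 0.005)   # uniform mean, CLT bound
  expect_identical(d, sample_reference_performance(a))  # seed determinism

  expect_error(reference_assumption(se_range = c(0.9, 0.8)), class = "pulpdx_bad_config")
  expect_error(reference_assumption(se_range = c(0, 0.8)), class = "pulpdx_bad_config")
})

test_that("algebraic inversion recovers truth and flags impossible solutions", {
  # perfect reference: corrected equals observed exactly
  ct <- confusion_table(6, 2, 0, 5)
  sol <- invert_misclassification(ct, 1, 1)
  expect_equal(sol$se_t, 1.0)
  expect_equal(sol$sp_t, 5 / 7, tolerance = 1e-12)
  expect_equal(sol$prevalence, 6 / 13, tolerance = 1e-12)
  expect_true(sol$valid)

  # exact recovery from noiselessly forward-composed rates
  grid <- expand.grid(prev = c(0.2, 0.5, 0.7), se_t = c(0.6, 0.8, 0.95),
                      sp_t = c(0.7, 0.9), se_r = c(0.8, 0.9), sp_r = c(0.7, 0.85))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    rates <- compose_observed_rates(g$prev, g$se_t, g$sp_t, g$se_r, g$sp_r)
    # feed the rates through a pseudo-table on a large denominator
    n <- 1e7
    ctg <- list(tp = rates$p11 * n, fp = rates$p10 * n,
                fn = (rates$q - rates$p11) * n,
                tn = (1 - rates$q - rates$p10) * n, n = n)
    sol <- invert_misclassification(ctg, g$se_r, g$sp_r)
    expect_equal(sol$se_t, g$se_t, tolerance = 1e-9)
    expect_equal(sol$sp_t, g$sp_t, tolerance = 1e-9)
    expect_equal(sol$prevalence, g$prev, tolerance = 1e-9)
  }

  # hand-solved invalid case on the published-style table
  sol <- invert_misclassification(confusion_table(6, 1, 0, 6), 0.825, 0.70)
  expect_false(sol$valid)
  expect_gt(sol$se_t, 1)   # solved sensitivity exceeds 1: impossible draw

  # prevalence numerator is monotone in sp_r
  ct <- confusion_table(6, 1, 0, 6)
  pis <- invert_misclassification(ct, rep(0.85, 5), seq(0.6, 0.8, length.out = 5))$prevalence
  expect_false(is.unsorted(pis))

  expect_error(invert_misclassification(ct, 0.5, 0.5), class = "pulpdx_bad_config")
})

test_that("label perturbation reduces to identity and to chance at the extremes", {
  fx <- canonical_fixture()
  # flip probabilities zero: exact identity with the apparent accuracy
  set.seed(1)
  out <- perturb_labels_correction(fx, 3.4, 1, 1)
  expect_equal(out$se_t, 1.0)
  expect_equal(out$sp_t, 6 / 7, tolerance = 1e-12)

  # deterministic under an outer seed
  r1 <- local({set.seed(42); perturb_labels_correction(fx, 3.4, 0.8, 0.7)})
  r2 <- local({set.seed(42); perturb_labels_correction(fx, 3.4, 0.8, 0.7)})
  expect_identical(r1, r2)

  # se_r = sp_r = 0.5 on a balanced cohort: labels carry no information,
  # corrected Se approaches the overall test-positive rate
  bal <- new_cohort(sprintf("B%02d", 1:20),
                    hs_crp = c(rep(5, 8), rep(1, 2), rep(5, 2), rep(1, 8)),
                    below_lod = FALSE, vas = 5,
                    pain_category = c(rep(3L, 10), rep(1L, 10)),
                    provenance = "synthetic")
  rate <- mean(bal$hs_crp >= 3)
  set.seed(7)
  ses <- vapply(1:4000, function(i) {
    perturb_labels_correction(bal, 3, 0.5, 0.5)$se_t
  }, numeric(1))
  expect_lt(abs(mean(ses) - rate), 0.02)
})

test_that("Monte Carlo correction summarises draws with full accounting", {
  fx <- canonical_fixture()

  # degenerate ranges at a perfect reference: medians equal observed
  for (model in c("algebraic_inversion", "label_perturbation")) {
    mc <- monte_carlo_correction(fx, 3.4, reference_assumption(
      se_range = c(1, 1), sp_range = c(1, 1), n_iterations = 300,
      model = model, seed = 5))
    expect_equal(unname(mc$corrected_se[["median"]]), 1.0, info = model)
    expect_equal(unname(mc$corrected_sp[["median"]]), 6 / 7, tolerance = 1e-12,
                 info = model)
    expect_equal(mc$n_invalid, 0)
    expect_equal(mc$model, model)
  }

  # published plausible ranges on the published-style table: invalid draws
  # exist and are fully accounted for
  mc <- monte_carlo_correction(fx, 3.4, reference_assumption(
    n_iterations = 2000, seed = 9))
  expect_gt(mc$n_invalid, 0)
  expect_equal(mc$n_valid + mc$n_invalid, 2000)
  expect_true(all(mc$corrected_se >= 0 & mc$corrected_se <= 1, na.rm = TRUE))

  # determinism, and draws retained on request
  mc2 <- monte_carlo_correction(fx, 3.4, reference_assumption(
    n_iterations = 2000, seed = 9), keep_draws = TRUE)
  expect_equal(mc$corrected_se, mc2$corrected_se)
  expect_equal(nrow(mc2$draws), 2000)
  expect_equal(sum(!mc2$draws$valid), mc$n_invalid)

  # discard and clip agree when no draw is invalid
  good <- reference_assumption(se_range = c(0.95, 1), sp_range = c(0.95, 1),
                               n_iterations = 500, seed = 21)
  ct_based <- monte_carlo_correction(fx, 2.9, good)
  good_clip <- good; good_clip$invalid_policy <- "clip"
  clip <- monte_carlo_correction(fx, 2.9, good_clip)
  if (ct_based$n_invalid == 0) {
    expect_equal(ct_based$corrected_se, clip$corrected_se)
    expect_equal(ct_based$corrected_sp, clip$corrected_sp)
  }

  # all-invalid pathway: flagged empty summary, not an error
  allbad <- monte_carlo_correction(
    new_cohort(c("a", "b"), c(5, 0), c(FALSE, TRUE), c(8, 2), c(3L, 1L),
               provenance = "synthetic"),
    3.4,
    reference_assumption(se_range = c(0.55, 0.56), sp_range = c(0.55, 0.56),
                         n_iterations = 50, seed = 2))
  if (allbad$n_valid == 0) {
    expect_true(allbad$empty)
    expect_true(is.na(allbad$corrected_se[["median"]]))
  }
})

test_that("parameter recovery from finite forward-simulated cohorts", {
  truth <- list(prev = 0.45, se_t = 0.85, sp_t = 0.8, se_r = 0.85, sp_r = 0.75)
  errs <- vapply(1:5, function(s) {
    ct <- simulate_imperfect_ct(2000, truth$prev, truth$se_t, truth$sp_t,
                                truth$se_r, truth$sp_r, seed = 100 + s)
    sol <- invert_misclassification(ct, truth$se_r, truth$sp_r)
    max(abs(c(sol$se_t - truth$se_t, sol$sp_t - truth$sp_t,
              sol$prevalence - truth$prev)))
  }, numeric(1))
  expect_true(all(errs < 0.05))
  expect_lt(stats::median(errs), 0.03)
})
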