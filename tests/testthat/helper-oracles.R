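# Independent oracles and random-case generators shared across tests.
# These deliberately use the slowest, most transparent formulation of each
# quantity so they stay independent of the package's computational routes.

# Pairwise Mann-Whitney AUC by explicit enumeration of all pos x neg pairs.
brute_auc <- function(pos, neg) {
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# All permutations of a vector (n <= 7), for exhaustive permutation tests.
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# A random valid cohort exercising censoring, ties and both flags.
random_cohort <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(5:40, 1)
  cat_ <- sample(0:3, n, replace = TRUE, prob = c(0.1, 0.2, 0.3, 0.4))
  crp <- round(rexp(n, 1 / 4), 2)
  below <- runif(n) < 0.25
  crp[below] <- 0
  below <- crp == 0
  over <- crp > 150
  crp[over] <- 200
  new_cohort(
    patient_id = sprintf("R%04d", seq_len(n)),
    hs_crp = crp,
    below_lod = below,
    vas = round(runif(n, 0, 10), 1),
    pain_category = cat_,
    tooth_type = sample(c("molar", "premolar", "incisor", "other", NA), n, replace = TRUE),
    over_range = over,
    provenance = "synthetic"
  )
}

# Forward simulation of the latent-disease misclassification model:
# disease ~ Bern(prev); index test and reference err independently given
# disease. Returns the apparent 2x2 of test vs observed reference.
simulate_imperfect_ct <- function(n, prev, se_t, sp_t, se_r, sp_r, seed) {
  set.seed(seed)
  d <- runif(n) < prev
  test <- ifelse(d, runif(n) < se_t, runif(n) > sp_t)
  ref <- ifelse(d, runif(n) < se_r, runif(n) > sp_r)
  confusion_table(
    tp = sum(test & ref), fp = sum(test & !ref),
    fn = sum(!test & ref), tn = sum(!test & !ref)
  )
}

# Cohorts whose reference split is guaranteed non-degenerate.
two_class_cohort <- function(seed, n = 30) {
  co <- random_cohort(seed, n)
  ref <- co$pain_category >= 3
  if (any(ref) && !all(ref)) return(co)
  co$pain_category[1] <- 3L
  co$pain_category[2] <- 0L
  co
}
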