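#' Cohort data model and CSV dialect
#'
#' A cohort is a data frame with one row per patient and columns
#' `patient_id` (character, unique), `hs_crp` (pulpal-blood hs-CRP in mg/L,
#' `>= 0`; values below the 0.5 mg/L detection limit are recorded as `0.0`),
#' `below_lod` (logical censoring flag, `TRUE` iff `hs_crp == 0`), `vas`
#' (visual analog pain score, cm, in `[0, 10]`), `pain_category` (ordinal
#' integer 0 = none, 1 = mild, 2 = moderate, 3 = severe), `tooth_type`
#' (optional; one of `"molar"`, `"premolar"`, `"incisor"`, `"other"` or
#' `NA`), and `over_range` (logical; `TRUE` iff the reading hit the 200 mg/L
#' assay ceiling). A `provenance` attribute records whether the cohort came
#' from a file, the synthetic generator, or the shipped fixture.
#'
#' @name cohort
NULL

COHORT_CSV_COLUMNS <- c("patient_id", "hs_crp_mg_l", "below_lod", "vas_cm",
                        "pain_category", "tooth_type")
TOOTH_TYPES <- c("molar", "premolar", "incisor", "other")
ASSAY_UPPER_LIMIT <- 200

#' Construct and validate a cohort
#'
#' @param patient_id Character vector of unique subject identifiers.
#' @param hs_crp Numeric hs-CRP concentrations (mg/L, `>= 0`).
#' @param below_lod Logical; `TRUE` iff the value is left-censored at the
#'   detection limit (stored as `0.0`).
#' @param vas Numeric VAS pain scores in `[0, 10]` (cm).
#' @param pain_category Integer ordinal pain category in `0:3`.
#' @param tooth_type Optional tooth type (`NA` allowed).
#' @param over_range Logical; reading clipped at the 200 mg/L assay ceiling.
#' @param provenance One of `"file"`, `"synthetic"`, `"fixture"`.
#' @return A validated cohort data frame (class `pulp_cohort`).
#' @export
new_cohort <- function(patient_id, hs_crp, below_lod, vas, pain_category,
                       tooth_type = NA_character_,
                       over_range = FALSE,
                       provenance = c("file", "synthetic", "fixture")) {
  provenance <- match.arg(provenance)
  df <- data.frame(
    patient_id = as.character(patient_id),
    hs_crp = as.numeric(hs_crp),
    below_lod = as.logical(below_lod),
    vas = as.numeric(vas),
    pain_category = as.integer(pain_category),
    tooth_type = rep_len(as.character(tooth_type), length(patient_id)),
    over_range = rep_len(as.logical(over_range), length(patient_id)),
    stringsAsFactors = FALSE
  )
  attr(df, "provenance") <- provenance
  class(df) <- c("pulp_cohort", "data.frame")
  validate_cohort(df)
}

#' Validate cohort invariants
#'
#' Checks the record-level invariants (censoring coding, assay range, score
#' ranges, joint presence of pain measures) and cohort-level invariants
#' (non-empty, unique identifiers). Each violation signals a condition with
#' a distinct class under `pulpdx_validation_error`.
#'
#' @param cohort A cohort data frame.
#' @return The cohort, invisibly unchanged, if valid.
#' @export
validate_cohort <- function(cohort) {
  req <- c("patient_id", "hs_crp", "below_lod", "vas", "pain_category")
  missing_cols <- setdiff(req, names(cohort))
  if (length(missing_cols) > 0) {
    abort_validation(
      sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
      "pulpdx_missing_column"
    )
  }
  if (nrow(cohort) < 1) {
    abort_validation("empty cohort", "pulpdx_empty_cohort")
  }
  if (anyDuplicated(cohort$patient_id)) {
    dup <- unique(cohort$patient_id[duplicated(cohort$patient_id)])
    abort_validation(
      sprintf("duplicate patient_id: %s", paste(dup, collapse = ", ")),
      "pulpdx_duplicate_id"
    )
  }
  if (!is.numeric(cohort$hs_crp) || anyNA(cohort$hs_crp)) {
    abort_validation("hs_crp must be numeric and non-missing", "pulpdx_bad_numeric")
  }
  bad <- which(cohort$hs_crp < 0)
  if (length(bad) > 0) {
    abort_validation(
      sprintf("negative hs_crp in row(s) %s", paste(bad, collapse = ", ")),
      "pulpdx_bad_value"
    )
  }
  over <- if ("over_range" %in% names(cohort)) cohort$over_range else FALSE
  bad <- which(cohort$hs_crp > ASSAY_UPPER_LIMIT & !over)
  if (length(bad) > 0) {
    abort_validation(
      sprintf("hs_crp above assay ceiling without over_range flag in row(s) %s",
              paste(bad, collapse = ", ")),
      "pulpdx_bad_value"
    )
  }
  # censoring coding: below_lod <=> stored 0.0
  mism <- which(xor(cohort$below_lod, cohort$hs_crp == 0))
  if (length(mism) > 0) {
    abort_validation(
      sprintf("below_lod flag inconsistent with hs_crp == 0 in row(s) %s",
              paste(mism, collapse = ", ")),
      "pulpdx_bad_value"
    )
  }
  if (anyNA(cohort$pain_category) || !all(cohort$pain_category %in% 0:3)) {
    bad <- which(is.na(cohort$pain_category) | !(cohort$pain_category %in% 0:3))
    abort_validation(
      sprintf("pain_category outside 0..3 in row(s) %s", paste(bad, collapse = ", ")),
      "pulpdx_bad_category"
    )
  }
  if (anyNA(cohort$vas) || any(cohort$vas < 0 | cohort$vas > 10)) {
    bad <- which(is.na(cohort$vas) | cohort$vas < 0 | cohort$vas > 10)
    abort_validation(
      sprintf("vas outside [0,10] or missing in row(s) %s", paste(bad, collapse = ", ")),
      "pulpdx_bad_value"
    )
  }
  tt <- cohort$tooth_type
  if (!is.null(tt)) {
    bad <- which(!is.na(tt) & !(tt %in% TOOTH_TYPES))
    if (length(bad) > 0) {
      abort_validation(
        sprintf("unknown tooth_type in row(s) %s", paste(bad, collapse = ", ")),
        "pulpdx_bad_value"
      )
    }
  }
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads the comma-separated, UTF-8 dialect with header
#' `patient_id,hs_crp_mg_l,below_lod,vas_cm,pain_category,tooth_type`
#' (`below_lod` coded 0/1; `tooth_type` may be empty; an optional trailing
#' `over_range` column, also 0/1, is honoured when present) and validates
#' every record.
#'
#' @param path Path to the CSV file.
#' @return A validated cohort with provenance `"file"`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("file not found: %s", path), "pulpdx_missing_file")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  missing_cols <- setdiff(setdiff(COHORT_CSV_COLUMNS, "tooth_type"), names(raw))
  if (length(missing_cols) > 0) {
    abort_validation(
      sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
      "pulpdx_missing_column"
    )
  }
  if (nrow(raw) == 0) {
    abort_validation("empty cohort", "pulpdx_empty_cohort")
  }
  num <- function(col, what) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !(is.na(raw[[col]]) | raw[[col]] == ""))
    if (length(bad) > 0) {
      abort_validation(
        sprintf("non-numeric %s in row(s) %s", what, paste(bad, collapse = ", ")),
        "pulpdx_bad_numeric"
      )
    }
    x
  }
  pain_raw <- suppressWarnings(as.integer(raw$pain_category))
  tooth <- if ("tooth_type" %in% names(raw)) {
    ifelse(raw$tooth_type == "" | is.na(raw$tooth_type), NA_character_, raw$tooth_type)
  } else {
    NA_character_
  }
  over <- if ("over_range" %in% names(raw)) num("over_range", "over_range") == 1 else FALSE
  new_cohort(
    patient_id = raw$patient_id,
    hs_crp = num("hs_crp_mg_l", "hs_crp"),
    below_lod = num("below_lod", "below_lod") == 1,
    vas = num("vas_cm", "vas"),
    pain_category = pain_raw,
    tooth_type = tooth,
    over_range = over,
    provenance = "file"
  )
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(c, p))` reproduces
#' `c` field-for-field. Concentrations are written with 17 significant
#' digits so doubles round-trip exactly; the `over_range` column is emitted
#' only when some record carries the flag.
#'
#' @param cohort A validated cohort.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  # shortest decimal form that parses back to the identical double
  g17 <- function(x) {
    s <- as.character(x)
    exact <- !is.na(x) & (as.numeric(s) == x)
    s[!exact] <- sprintf("%.17g", x[!exact])
    s
  }
  out <- data.frame(
    patient_id = cohort$patient_id,
    hs_crp_mg_l = g17(cohort$hs_crp),
    below_lod = as.integer(cohort$below_lod),
    vas_cm = g17(cohort$vas),
    pain_category = cohort$pain_category,
    tooth_type = ifelse(is.na(cohort$tooth_type), "", cohort$tooth_type),
    stringsAsFactors = FALSE
  )
  if (any(cohort$over_range)) out$over_range <- as.integer(cohort$over_range)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_validation(sprintf("cannot write to %s", path), "pulpdx_unwritable_path")
  invisible(path)
}

#' The canonical 13-patient fixture
#'
#' A fixed cohort reconstructed from the published summary constraints of
#' the pilot study: 2 mild, 5 moderate and 6 severe patients; four
#' non-severe values undetectable (recorded 0.0); every severe value at or
#' above 3.4 mg/L with exactly one in `[3.4, 3.5)`; exactly two non-severe
#' values at or above 2.9 mg/L, of which exactly one is at or above 3.5;
#' maximum 18.0 mg/L. The raw per-patient values were never published, so
#' this is a synthetic reconstruction: it reproduces the classification
#' pattern behind the published 2x2 tables exactly, but not every printed
#' summary (its hs-CRP median is 3.45 mg/L, not the published 2.9 — the two
#' are mutually inconsistent and the classification pattern is
#' prioritised). Rank-based statistics on it (e.g. Spearman rho about 0.76)
#' are therefore qualitative, not numeric reproductions.
#'
#' @return A 13-row cohort with provenance `"fixture"`.
#' @export
#' @examples
#' fx <- canonical_fixture()
#' table(fx$pain_category)
#' max(fx$hs_crp)
canonical_fixture <- function() {
  new_cohort(
    patient_id = sprintf("P%02d", 1:13),
    hs_crp = c(0, 0,
               0, 0, 1, 3, 8,
               3.45, 3.6, 4, 5.5, 9, 18),
    below_lod = c(TRUE, TRUE,
                  TRUE, TRUE, FALSE, FALSE, FALSE,
                  rep(FALSE, 6)),
    vas = c(2, 3,
            4.5, 5, 5.5, 6, 6.5,
            7.5, 8, 8.5, 9, 9.5, 10),
    pain_category = c(1L, 1L, rep(2L, 5), rep(3L, 6)),
    tooth_type = c("molar", "premolar",
                   "molar", "molar", "premolar", "premolar", "incisor",
                   "molar", "molar", "molar", "molar", "molar", "premolar"),
    provenance = "fixture"
  )
}

#' Summarize a cohort
#'
#' Descriptive summary in the style of a pilot-study baseline table:
#' category counts, hs-CRP median/quartiles/maximum (censored values enter
#' as 0.0) and VAS mean and SD.
#'
#' @param cohort A validated cohort.
#' @param quartile_type Quantile rule, passed to [stats::quantile()];
#'   default 7 (linear interpolation of order statistics).
#' @return A list with `n`, `category_counts`, `crp_median`, `crp_q1`,
#'   `crp_q3`, `crp_max`, `vas_mean`, `vas_sd`, `quartile_type`.
#' @export
summarize_cohort <- function(cohort, quartile_type = 7) {
  validate_cohort(cohort)
  q <- stats::quantile(cohort$hs_crp, probs = c(0.25, 0.5, 0.75),
                       type = quartile_type, names = FALSE)
  list(
    n = nrow(cohort),
    category_counts = vapply(0:3, function(k) sum(cohort$pain_category == k), integer(1)),
    crp_median = q[2],
    crp_q1 = q[1],
    crp_q3 = q[3],
    crp_max = max(cohort$hs_crp),
    vas_mean = mean(cohort$vas),
    vas_sd = stats::sd(cohort$vas),
    quartile_type = quartile_type
  )
}
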