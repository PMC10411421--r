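#' Patients with a creatinine result in the lookback window
#'
#' The denominator population for prevalence estimates: enrollees with at
#' least one valid serum-creatinine measurement in the `lookback_days`
#' window ending at the reference date.
#'
#' @param registry An `ehr_registry`.
#' @param lookback_days Window length, default 365.
#' @return Sorted character vector of patient ids.
#' @export
creatinine_tested_users <- function(registry, lookback_days = 365) {
  stopifnot(inherits(registry, "ehr_registry"))
  ref <- registry$reference_date
  labs <- registry$labs
  keep <- labs$collection_date >= ref - lookback_days &
    labs$collection_date <= ref & labs$creatinine_mg_dl > 0
  sort(unique(labs$patient_id[keep]))
}

#' Split candidates by dialysis/ESKD codes
#'
#' Removes candidates carrying any dialysis ICD-10 or CPT code within the
#' lookback window (diagnosis and procedure tables are both scanned).
#'
#' @param candidates Character vector of patient ids.
#' @param registry An `ehr_registry`.
#' @param dialysis_codes A [code_set] of dialysis/ESKD codes.
#' @param lookback_days Window length ending at the reference date.
#' @return List with sorted id vectors `kept` and `excluded`
#'   (`kept` and `excluded` partition `candidates`).
#' @export
exclude_dialysis <- function(candidates, registry, dialysis_codes,
                             lookback_days = 365) {
  stopifnot(inherits(registry, "ehr_registry"))
  ref <- registry$reference_date
  coded <- union(
    match_codes(registry$diagnoses, dialysis_codes, ref - lookback_days, ref),
    match_codes(registry$procedures, dialysis_codes, ref - lookback_days, ref)
  )
  excluded <- sort(intersect(candidates, coded))
  list(kept = sort(setdiff(candidates, excluded)), excluded = excluded)
}

#' Build the advanced-CKD source cohort
#'
#' Reproduces the extraction flow: active enrollees, creatinine-tested
#' users, then the source cohort of patients who either have an index eGFR
#' at or below the threshold (eGFR arm) or an advanced-CKD diagnosis code in
#' the lookback window (code arm), minus dialysis/ESKD exclusions. The eGFR
#' arm uses a non-strict threshold (<= 30) by default while the tier
#' classifier and comparator phenotypes use strict < 30 comparisons; both
#' conventions appear in the field and the inclusive/strict choice is a
#' switch here.
#'
#' Code-arm members with no creatinine lab in the window are retained but
#' carry `NA` eGFR columns — they are classifiable only as `unclassified`.
#'
#' @param registry An `ehr_registry`.
#' @param adv_ckd_codes,dialysis_codes,aki_codes [code_set]s; defaults from
#'   [default_code_sets()].
#' @param egfr_threshold eGFR-arm inclusion threshold, default 30
#'   ml/min/1.73 m^2.
#' @param egfr_inclusive Use `<=` (default) rather than `<` for the
#'   eGFR arm.
#' @param lookback_days,min_gap_days Window parameters (365 / 90 days).
#' @return A `ckd_cohort`: list with `cohort` (tibble: `patient_id`,
#'   `egfr_arm`, `code_arm`, index/prior eGFR and dates), `pairs` (all
#'   tested users' eGFR pairs), `tested` (denominator ids), `flow`
#'   (a `cohort_flow` of attrition counts) and the configuration used.
#' @export
build_source_cohort <- function(registry,
                                adv_ckd_codes = NULL,
                                dialysis_codes = NULL,
                                aki_codes = NULL,
                                egfr_threshold = 30,
                                egfr_inclusive = TRUE,
                                lookback_days = 365,
                                min_gap_days = 90) {
  stopifnot(inherits(registry, "ehr_registry"))
  sets <- default_code_sets()
  adv_ckd_codes <- adv_ckd_codes %||% sets$advanced_ckd
  dialysis_codes <- dialysis_codes %||% sets$dialysis
  aki_codes <- aki_codes %||% sets$aki
  if (!"egfr" %in% names(registry$labs)) {
    registry <- add_egfr(registry)
  }
  ref <- registry$reference_date
  active <- sort(registry$patients$patient_id[registry$patients$enrolled %in% TRUE])
  tested <- intersect(creatinine_tested_users(registry, lookback_days), active)
  pairs <- select_egfr_pairs(registry, lookback_days, min_gap_days)
  pairs <- pairs[pairs$patient_id %in% active, , drop = FALSE]

  in_egfr_arm <- if (egfr_inclusive) {
    pairs$index_egfr <= egfr_threshold
  } else {
    pairs$index_egfr < egfr_threshold
  }
  egfr_arm <- pairs$patient_id[in_egfr_arm]
  code_arm <- intersect(
    match_codes(registry$diagnoses, adv_ckd_codes, ref - lookback_days, ref),
    active
  )
  candidates <- sort(union(egfr_arm, code_arm))
  split <- exclude_dialysis(candidates, registry, dialysis_codes, lookback_days)

  cohort <- tibble(patient_id = split$kept) |>
    mutate(
      egfr_arm = .data$patient_id %in% egfr_arm,
      code_arm = .data$patient_id %in% code_arm
    ) |>
    left_join(pairs, by = "patient_id")

  flow <- structure(
    list(
      n_active = length(active),
      n_tested = length(tested),
      n_egfr_arm = length(unique(egfr_arm)),
      n_code_arm = length(code_arm),
      n_candidates = length(candidates),
      n_excluded_dialysis = length(split$excluded),
      n_source = nrow(cohort),
      ids = list(
        tested = tested, candidates = candidates,
        excluded_dialysis = split$excluded, source = cohort$patient_id
      )
    ),
    class = "cohort_flow"
  )
  structure(
    list(
      cohort = cohort, pairs = pairs, tested = tested, flow = flow,
      reference_date = ref,
      config = list(
        egfr_threshold = egfr_threshold, egfr_inclusive = egfr_inclusive,
        lookback_days = lookback_days, min_gap_days = min_gap_days,
        adv_ckd_codes = adv_ckd_codes, dialysis_codes = dialysis_codes,
        aki_codes = aki_codes
      )
    ),
    class = "ckd_cohort"
  )
}

#' @export
print.cohort_flow <- function(x, ...) {
  cat("Cohort attrition flow\n")
  cat(sprintf("  active enrollees:              %d\n", x$n_active))
  cat(sprintf("  with creatinine in lookback:   %d\n", x$n_tested))
  cat(sprintf("  eGFR arm (index <= threshold): %d\n", x$n_egfr_arm))
  cat(sprintf("  code arm (advanced-CKD ICD):   %d\n", x$n_code_arm))
  cat(sprintf("  candidates (either arm):       %d\n", x$n_candidates))
  cat(sprintf("  excluded dialysis/ESKD:        %d\n", x$n_excluded_dialysis))
  cat(sprintf("  source cohort:                 %d\n", x$n_source))
  invisible(x)
}

#' @export
print.ckd_cohort <- function(x, ...) {
  cat(
    "<ckd_cohort> as of", format(x$reference_date), "-",
    nrow(x$cohort), "members\n"
  )
  print(x$flow)
  invisible(x)
}
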