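#' Run the full phenotyping pipeline and write a report bundle
#'
#' Orchestrates every stage on one registry: eGFR computation, cohort
#' extraction with dialysis exclusion, tier assignment, comparator
#' phenotypes, prevalence and diagnostic-accuracy tables, six-month
#' follow-up stability, gap statistics and the cumulative-prevalence scan.
#' All outputs are written as delimited text plus a machine-readable JSON
#' manifest recording the configuration, so a run is reproducible and every
#' report row traces back to patient-level evidence in the assignment
#' table.
#'
#' @param registry An `ehr_registry`, or a directory path readable by
#'   [read_registry()].
#' @param out_dir Output directory; created if needed. `NULL` skips
#'   writing.
#' @param code_sets Named list of [code_set]s (`advanced_ckd`, `dialysis`,
#'   `aki`); defaults from [default_code_sets()].
#' @param egfr_threshold,egfr_inclusive,lookback_days,min_gap_days,horizon_days
#'   Pipeline thresholds (defaults 30, inclusive, 365, 90, 180).
#' @param ci_method `"wilson"` or `"wald"`.
#' @return Invisibly, a named list with `flow`, `assignments`,
#'   `phenotypes`, `prevalence`, `accuracy`, `followup`, `gaps`,
#'   `cumulative`, `manifest`.
#' @export
run_pipeline <- function(registry, out_dir = NULL,
                         code_sets = default_code_sets(),
                         egfr_threshold = 30, egfr_inclusive = TRUE,
                         lookback_days = 365, min_gap_days = 90,
                         horizon_days = 180,
                         ci_method = c("wilson", "wald")) {
  ci_method <- match.arg(ci_method)
  if (is.character(registry)) {
    registry <- read_registry(registry, horizon_days = horizon_days)
  }
  stopifnot(inherits(registry, "ehr_registry"))
  registry <- add_egfr(registry)

  cohort <- build_source_cohort(registry,
    adv_ckd_codes = code_sets$advanced_ckd,
    dialysis_codes = code_sets$dialysis,
    aki_codes = code_sets$aki,
    egfr_threshold = egfr_threshold, egfr_inclusive = egfr_inclusive,
    lookback_days = lookback_days, min_gap_days = min_gap_days
  )
  assignments <- assign_tiers(cohort, registry)

  phen_names <- c("icd_only", "single_egfr", "two_egfr")
  phenotypes <- lapply(phen_names, function(p) apply_phenotype(cohort, registry, p))
  names(phenotypes) <- phen_names
  positives <- lapply(phenotypes, function(tab) tab$patient_id[tab$label %in% TRUE])
  positives$high <- assignments$patient_id[assignments$tier == "high"]
  positives$high_intermediate <- assignments$patient_id[
    assignments$tier %in% c("high", "intermediate")
  ]

  denom <- length(cohort$tested)
  prev <- bind_rows(lapply(names(positives), function(p) {
    est <- prevalence(length(positives[[p]]), denom, ci_method = ci_method)
    est$phenotype <- p
    as_tibble(unclass(est))
  }))
  prev <- prev[c("phenotype", setdiff(names(prev), "phenotype"))]

  refs <- c("single_egfr", "two_egfr", "high", "high_intermediate")
  acc <- bind_rows(lapply(refs, function(r) {
    universe <- cohort$tested
    ct <- confusion(
      intersect(positives$icd_only, universe),
      intersect(positives[[r]], universe), universe
    )
    stats <- accuracy_stats(ct, ci_method = ci_method)
    stats$reference <- r
    stats
  }))

  groups <- c(
    list(source_cohort = cohort$cohort$patient_id),
    positives[c("icd_only", "single_egfr", "two_egfr")],
    list(
      high = positives$high,
      intermediate = assignments$patient_id[assignments$tier == "intermediate"],
      low = assignments$patient_id[assignments$tier == "low"]
    )
  )
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  fu <- followup_stats(groups, registry, cohort$pairs, horizon_days = horizon_days)
  gaps <- gap_statistics(groups, cohort$pairs)
  cumulative <- cumulative_prevalence(registry,
    snapshot_days = seq(0, horizon_days, by = 30),
    adv_ckd_codes = code_sets$advanced_ckd,
    dialysis_codes = code_sets$dialysis,
    aki_codes = code_sets$aki,
    egfr_threshold = egfr_threshold, egfr_inclusive = egfr_inclusive,
    lookback_days = lookback_days, min_gap_days = min_gap_days
  )

  manifest <- list(
    package = "ckdtier",
    version = as.character(utils::packageVersion("ckdtier")),
    reference_date = format(registry$reference_date),
    n_patients = nrow(registry$patients),
    config = list(
      egfr_threshold = egfr_threshold, egfr_inclusive = egfr_inclusive,
      lookback_days = lookback_days, min_gap_days = min_gap_days,
      horizon_days = horizon_days, ci_method = ci_method,
      code_sets = lapply(code_sets, function(cs) cs[c("icd10", "cpt")])
    ),
    flow = cohort$flow[c(
      "n_active", "n_tested", "n_egfr_arm", "n_code_arm",
      "n_candidates", "n_excluded_dialysis", "n_source"
    )]
  )

  out <- list(
    flow = cohort$flow, cohort = cohort, assignments = assignments,
    phenotypes = phenotypes, prevalence = prev, accuracy = acc,
    followup = fu, gaps = gaps, cumulative = cumulative,
    manifest = manifest
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    flow_tab <- tibble(
      stage = c(
        "active_enrollees", "creatinine_tested", "egfr_arm", "code_arm",
        "candidates", "excluded_dialysis", "source_cohort"
      ),
      n = unlist(manifest$flow, use.names = FALSE)
    )
    readr::write_csv(flow_tab, file.path(out_dir, "cohort_flow.csv"))
    readr::write_csv(assignments, file.path(out_dir, "assignments.csv"))
    readr::write_csv(prev, file.path(out_dir, "prevalence.csv"))
    readr::write_csv(acc, file.path(out_dir, "accuracy.csv"))
    readr::write_csv(fu, file.path(out_dir, "followup.csv"))
    readr::write_csv(gaps, file.path(out_dir, "gap_statistics.csv"))
    readr::write_csv(cumulative$per_snapshot, file.path(out_dir, "cumulative_snapshots.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(out)
}
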