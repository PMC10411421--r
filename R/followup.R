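#' Six-month follow-up stability of phenotype groups
#'
#' For each named group of patients, summarises the eGFR behaviour over the
#' follow-up horizon after each patient's index date:
#'
#' * `n_subsequent` — patients with at least one eGFR measured after their
#'   index date and no later than `reference_date + horizon_days`
#'   (percent of the whole group);
#' * `n_any_ge30` — patients with *any* such follow-up eGFR at or above the
#'   threshold (percent of the whole group);
#' * `n_current_ge30` — patients whose *latest* follow-up eGFR is at or
#'   above the threshold (percent of those with a follow-up measurement;
#'   same-day ties resolved to the lowest value);
#' * `pct_remaining` — `100 - pct_current_ge30`, the probability of
#'   remaining in the advanced-CKD stage, defined only when
#'   `n_subsequent > 0`.
#'
#' Note the deliberate difference in denominators: `pct_any_ge30` is over
#' the whole group while `pct_current_ge30` is over patients with a
#' follow-up value, so `n_current_ge30 > n_any_ge30` percentages can
#' coexist.
#'
#' @param groups Named list of patient-id character vectors (e.g. tiers or
#'   comparator-phenotype positives).
#' @param registry The `ehr_registry` (labs must cover the follow-up
#'   horizon; eGFR computed on the fly if absent).
#' @param pairs eGFR-pair tibble from [select_egfr_pairs()] (supplies each
#'   patient's index date).
#' @param horizon_days Follow-up horizon after the reference date,
#'   default 180.
#' @param threshold Stage boundary, default 30 ml/min/1.73 m^2.
#' @return Tibble with one row per group: counts and percentages as above.
#'   Empty groups are dropped with a warning.
#' @export
followup_stats <- function(groups, registry, pairs, horizon_days = 180,
                           threshold = 30) {
  stopifnot(inherits(registry, "ehr_registry"), is.list(groups))
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort("`groups` must be a named list of patient-id vectors.")
  }
  empty <- vapply(groups, length, integer(1)) == 0
  if (any(empty)) {
    warn(sprintf("Dropping empty group(s): %s", paste(names(groups)[empty], collapse = ", ")))
    groups <- groups[!empty]
  }
  if (!"egfr" %in% names(registry$labs)) {
    registry <- add_egfr(registry)
  }
  end <- registry$reference_date + horizon_days
  labs <- registry$labs
  idx_date <- pairs$index_date[match(labs$patient_id, pairs$patient_id)]
  fu <- labs[!is.na(idx_date) & labs$collection_date > idx_date &
    labs$collection_date <= end, , drop = FALSE]
  per_patient <- if (nrow(fu) == 0) {
    tibble(
      patient_id = character(), any_ge = logical(),
      last_date = as.Date(character()), current = numeric()
    )
  } else {
    fu |>
      group_by(.data$patient_id) |>
      summarise(
        any_ge = any(.data$egfr >= threshold),
        last_date = max(.data$collection_date),
        current = min(.data$egfr[.data$collection_date == last_date]),
        .groups = "drop"
      )
  }
  rows <- lapply(names(groups), function(g) {
    ids <- unique(as.character(groups[[g]]))
    pp <- per_patient[per_patient$patient_id %in% ids, , drop = FALSE]
    n_sub <- nrow(pp)
    n_any <- sum(pp$any_ge)
    n_cur <- sum(pp$current >= threshold)
    tibble(
      group = g,
      n_group = length(ids),
      n_subsequent = n_sub,
      pct_subsequent = 100 * n_sub / length(ids),
      n_any_ge30 = n_any,
      pct_any_ge30 = 100 * n_any / length(ids),
      n_current_ge30 = n_cur,
      pct_current_ge30 = if (n_sub > 0) 100 * n_cur / n_sub else NA_real_,
      pct_remaining = if (n_sub > 0) 100 - 100 * n_cur / n_sub else NA_real_
    )
  })
  bind_rows(rows)
}

#' Gap between the stage-defining eGFR values, per group
#'
#' Mean and sample standard deviation of `index_date - prior_date` in days
#' over the members of each group that have both values.
#'
#' @param groups Named list of patient-id vectors.
#' @param pairs eGFR-pair tibble from [select_egfr_pairs()].
#' @return Tibble: `group`, `n_pairs`, `mean_gap_days`, `sd_gap_days`
#'   (`NA` when fewer than two pairs).
#' @export
gap_statistics <- function(groups, pairs) {
  rows <- lapply(names(groups), function(g) {
    ids <- unique(as.character(groups[[g]]))
    gaps <- pairs$gap_days[pairs$patient_id %in% ids & !is.na(pairs$gap_days)]
    tibble(
      group = g,
      n_pairs = length(gaps),
      mean_gap_days = if (length(gaps)) mean(gaps) else NA_real_,
      sd_gap_days = if (length(gaps) > 1) stats::sd(gaps) else NA_real_
    )
  })
  bind_rows(rows)
}

#' Cumulative prevalence over monthly re-extractions
#'
#' Re-runs cohort extraction and tier assignment at monthly snapshots over
#' the follow-up horizon and accumulates the union of patients who ever
#' qualify as high- or intermediate-risk, over the fixed creatinine-tested
#' denominator of the initial extraction.
#'
#' @param registry An `ehr_registry` whose labs extend through the horizon.
#' @param snapshot_days Offsets (days) from the reference date at which the
#'   extraction is repeated; default `seq(0, 180, by = 30)`.
#' @param tiers Tiers counted as advanced CKD, default
#'   `c("high", "intermediate")`.
#' @param ... Passed to [build_source_cohort()].
#' @return List: `estimate` (a [prevalence()] row), `ids` (the accumulated
#'   patient ids), `per_snapshot` (tibble of counts per snapshot).
#' @export
cumulative_prevalence <- function(registry, snapshot_days = seq(0, 180, by = 30),
                                  tiers = c("high", "intermediate"), ...) {
  stopifnot(inherits(registry, "ehr_registry"))
  denom <- creatinine_tested_users(registry)
  acc <- character()
  snaps <- lapply(snapshot_days, function(d) {
    snap <- registry
    snap$reference_date <- registry$reference_date + d
    cohort <- build_source_cohort(snap, ...)
    assign <- assign_tiers(cohort, snap)
    ids <- assign$patient_id[assign$tier %in% tiers]
    acc <<- union(acc, ids)
    tibble(
      offset_days = d, n_qualifying = length(ids),
      n_cumulative = length(acc)
    )
  })
  list(
    estimate = prevalence(length(acc), length(denom)),
    ids = sort(acc),
    per_snapshot = bind_rows(snaps)
  )
}
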