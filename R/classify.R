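tier_levels <- c("high", "intermediate", "low", "excluded_aki", "unclassified")

#' Tier a patient from two eGFR values, codes and AKI history
#'
#' The tiered advanced-CKD phenotype, as a pure vectorised function of the
#' index eGFR, the >= 90-day-prior eGFR, the presence of an advanced-CKD
#' diagnosis code, and an AKI diagnosis within 90 days before the index
#' value:
#'
#' * **high**: index < 30 and prior < 30;
#' * **intermediate, subgroup 1**: index < 30, prior in \[30, 60), no
#'   recent AKI; with recent AKI the patient is carved out as
#'   **excluded_aki**;
#' * **intermediate, subgroup 2**: index in \[30, 60), prior < 30, and an
#'   advanced-CKD code;
#' * **low**: index >= 30, prior >= 30, and an advanced-CKD code;
#' * **unclassified**: every other combination, including a missing prior
#'   value.
#'
#' The tiers are mutually exclusive and cover all inputs. Thresholds are
#' compared at full precision (no rounding), in ml/min/1.73 m^2.
#'
#' @param index_egfr Index (latest) eGFR; must be non-missing.
#' @param prior_egfr Prior eGFR, `NA` when absent.
#' @param has_adv_code Logical, advanced-CKD diagnosis code in the lookback.
#' @param aki_in_90d Logical, AKI code within 90 days before the index date.
#' @param lower,upper Stage thresholds (30 and 60 ml/min/1.73 m^2).
#' @param detail Return a tibble with `tier` and intermediate `subgroup`
#'   instead of a bare factor.
#' @return Factor with levels high/intermediate/low/excluded_aki/
#'   unclassified (or a tibble when `detail = TRUE`).
#' @examples
#' classify_tier(25, 28, FALSE, FALSE) # high
#' classify_tier(25, 45, FALSE, TRUE) # excluded_aki
#' classify_tier(40, 25, TRUE, FALSE) # intermediate (subgroup 2)
#' @export
classify_tier <- function(index_egfr, prior_egfr, has_adv_code, aki_in_90d,
                          lower = 30, upper = 60, detail = FALSE) {
  if (any(is.na(index_egfr))) {
    abort("`index_egfr` must be non-missing; patients without an index eGFR are not classifiable.")
  }
  n <- length(index_egfr)
  prior_egfr <- rep_len(prior_egfr, n)
  has_adv_code <- rep_len(as.logical(has_adv_code), n)
  aki_in_90d <- rep_len(as.logical(aki_in_90d), n)
  has_prior <- !is.na(prior_egfr)
  i_lo <- index_egfr < lower
  i_mid <- index_egfr >= lower & index_egfr < upper
  p_lo <- has_prior & prior_egfr < lower
  p_mid <- has_prior & prior_egfr >= lower & prior_egfr < upper
  p_ge <- has_prior & prior_egfr >= lower

  tier <- rep("unclassified", n)
  subgroup <- rep(NA_integer_, n)
  tier[i_lo & p_lo] <- "high"
  sub1 <- i_lo & p_mid & !aki_in_90d
  tier[sub1] <- "intermediate"
  subgroup[sub1] <- 1L
  tier[i_lo & p_mid & aki_in_90d] <- "excluded_aki"
  sub2 <- i_mid & p_lo & has_adv_code
  tier[sub2] <- "intermediate"
  subgroup[sub2] <- 2L
  tier[index_egfr >= lower & p_ge & has_adv_code] <- "low"
  tier <- factor(tier, levels = tier_levels)
  if (detail) {
    tibble(tier = tier, subgroup = subgroup)
  } else {
    tier
  }
}

#' Assign tiers across a source cohort
#'
#' Applies [classify_tier()] to every cohort member, deriving the AKI flag
#' from N17-family diagnoses dated within `aki_window_days` before that
#' patient's index eGFR date (closed interval). Members without an index
#' eGFR (code-arm members with no lab in the window) are `unclassified`.
#'
#' @param cohort A `ckd_cohort` from [build_source_cohort()].
#' @param registry The `ehr_registry` the cohort was built from.
#' @param aki_window_days AKI lookback before the index date, default 90.
#' @return Tibble: `patient_id`, `tier`, `subgroup`, `index_egfr`,
#'   `index_date`, `prior_egfr`, `prior_date`, `has_adv_code`,
#'   `aki_in_90d`.
#' @export
assign_tiers <- function(cohort, registry, aki_window_days = 90) {
  stopifnot(inherits(cohort, "ckd_cohort"), inherits(registry, "ehr_registry"))
  members <- cohort$cohort
  aki_set <- cohort$config$aki_codes
  aki_flag <- rep(FALSE, nrow(members))
  has_index <- !is.na(members$index_egfr)
  if (any(has_index) && nrow(registry$diagnoses) > 0) {
    dx <- registry$diagnoses
    dx <- dx[dx$system == "ICD10", , drop = FALSE]
    is_aki <- Reduce(
      `|`,
      lapply(aki_set$icd10, function(p) startsWith(normalize_icd10(dx$code), p)),
      init = rep(FALSE, nrow(dx))
    )
    dx <- dx[is_aki, , drop = FALSE]
    if (nrow(dx) > 0) {
      idx_date <- members$index_date[match(dx$patient_id, members$patient_id)]
      in_win <- !is.na(idx_date) &
        dx$event_date >= idx_date - aki_window_days &
        dx$event_date <= idx_date
      aki_ids <- unique(dx$patient_id[in_win])
      aki_flag <- members$patient_id %in% aki_ids
    }
  }
  det <- tibble(
    tier = factor(rep("unclassified", nrow(members)), levels = tier_levels),
    subgroup = NA_integer_
  )
  if (any(has_index)) {
    det[has_index, ] <- classify_tier(
      members$index_egfr[has_index],
      members$prior_egfr[has_index],
      members$code_arm[has_index],
      aki_flag[has_index],
      lower = 30, upper = 60,
      detail = TRUE
    )
  }
  tibble(
    patient_id = members$patient_id,
    tier = det$tier,
    subgroup = det$subgroup,
    index_egfr = members$index_egfr,
    index_date = members$index_date,
    prior_egfr = members$prior_egfr,
    prior_date = members$prior_date,
    has_adv_code = members$code_arm,
    aki_in_90d = aki_flag
  )
}

#' Apply a comparator or tiered phenotype
#'
#' Evaluates one of the published advanced-CKD phenotype definitions over a
#' built cohort:
#'
#' * `icd_only` — positive iff an advanced-CKD diagnosis code in the
#'   lookback window;
#' * `single_egfr` — positive iff index eGFR < 30;
#' * `two_egfr` — positive iff index eGFR < 30 and prior eGFR < 60;
#'   patients missing a prior value get `NA` (excluded from two-eGFR
#'   denominators);
#' * `tiered` — the [classify_tier()] label.
#'
#' @param cohort A `ckd_cohort`.
#' @param registry The registry (needed for `tiered`'s AKI flag).
#' @param phenotype One of `"icd_only"`, `"single_egfr"`, `"two_egfr"`,
#'   `"tiered"`.
#' @return Tibble `patient_id`, `label`: logical for the comparators, the
#'   tier factor for `tiered`.
#' @export
apply_phenotype <- function(cohort, registry,
                            phenotype = c("icd_only", "single_egfr", "two_egfr", "tiered")) {
  stopifnot(inherits(cohort, "ckd_cohort"))
  if (length(phenotype) != 1 || !phenotype %in% c("icd_only", "single_egfr", "two_egfr", "tiered")) {
    abort("`phenotype` must be one of icd_only, single_egfr, two_egfr, tiered.")
  }
  m <- cohort$cohort
  if (phenotype == "tiered") {
    a <- assign_tiers(cohort, registry)
    return(tibble(patient_id = a$patient_id, label = a$tier))
  }
  label <- switch(phenotype,
    icd_only = m$code_arm,
    single_egfr = !is.na(m$index_egfr) & m$index_egfr < 30,
    two_egfr = ifelse(is.na(m$index_egfr) | is.na(m$prior_egfr), NA,
      m$index_egfr < 30 & m$prior_egfr < 60
    )
  )
  tibble(patient_id = m$patient_id, label = as.logical(label))
}
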