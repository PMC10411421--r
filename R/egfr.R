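#' MDRD estimated glomerular filtration rate
#'
#' Four-variable MDRD study equation (IDMS-traceable re-expression):
#' \deqn{eGFR = 175 \times Scr^{-1.154} \times age^{-0.203} \times 0.742_{[female]} \times 1.212_{[Black]}}
#' in ml/min/1.73 m^2. The leading coefficient is configurable (the older
#' non-IDMS form used 186); all other constants are fixed by the equation.
#'
#' @param creatinine_mg_dl Serum creatinine in mg/dL (> 0).
#' @param age_years Age at the time of measurement in years (> 0).
#' @param sex `"male"` or `"female"` (vectorised).
#' @param race_black Logical; Black race per the original equation's
#'   coefficient.
#' @param coefficient Leading coefficient, default 175.
#' @return eGFR in ml/min/1.73 m^2, strictly decreasing in both creatinine
#'   and age.
#' @examples
#' compute_egfr_mdrd(2.5, 60, "male", FALSE) # ~26.5
#' @export
compute_egfr_mdrd <- function(creatinine_mg_dl, age_years, sex,
                              race_black = FALSE, coefficient = 175) {
  if (any(is.na(creatinine_mg_dl)) || any(creatinine_mg_dl <= 0)) {
    abort("`creatinine_mg_dl` must be positive.")
  }
  if (any(is.na(age_years)) || any(age_years <= 0)) {
    abort("`age_years` must be positive.")
  }
  bad_sex <- !sex %in% c("male", "female")
  if (any(bad_sex)) {
    abort(sprintf("Unknown sex value(s): %s", paste(unique(sex[bad_sex]), collapse = ", ")))
  }
  coefficient * creatinine_mg_dl^-1.154 * age_years^-0.203 *
    ifelse(sex == "female", 0.742, 1) * ifelse(race_black, 1.212, 1)
}

#' Invert the MDRD equation for serum creatinine
#'
#' Returns the creatinine value that yields a target eGFR for the given
#' demographics — the algebraic inverse of [compute_egfr_mdrd()], used by
#' the synthetic generator to turn simulated eGFR trajectories into lab
#' values.
#'
#' @inheritParams compute_egfr_mdrd
#' @param egfr Target eGFR in ml/min/1.73 m^2 (> 0).
#' @return Serum creatinine in mg/dL.
#' @examples
#' scr <- invert_mdrd(29.9, 75, "male", FALSE)
#' compute_egfr_mdrd(scr, 75, "male", FALSE) # 29.9
#' @export
invert_mdrd <- function(egfr, age_years, sex, race_black = FALSE,
                        coefficient = 175) {
  if (any(is.na(egfr)) || any(egfr <= 0)) {
    abort("`egfr` must be positive.")
  }
  if (any(is.na(age_years)) || any(age_years <= 0)) {
    abort("`age_years` must be positive.")
  }
  demo <- coefficient * age_years^-0.203 *
    ifelse(sex == "female", 0.742, 1) * ifelse(race_black, 1.212, 1)
  (egfr / demo)^(-1 / 1.154)
}

#' Fill the eGFR column of a registry's lab table
#'
#' Computes MDRD eGFR for every creatinine result using the patient's sex,
#' race and age. Age is taken at the collection date when `birth_date` is
#' available (in fractional years, 365.25-day years), otherwise the fixed
#' `age_years` at the reference date is used.
#'
#' @param registry An `ehr_registry`.
#' @param coefficient Passed to [compute_egfr_mdrd()].
#' @return The registry with `labs$egfr` filled.
#' @export
add_egfr <- function(registry, coefficient = 175) {
  stopifnot(inherits(registry, "ehr_registry"))
  labs <- registry$labs
  if (nrow(labs) == 0) {
    labs$egfr <- numeric()
    registry$labs <- labs
    return(registry)
  }
  idx <- match(labs$patient_id, registry$patients$patient_id)
  p <- registry$patients[idx, , drop = FALSE]
  age <- patient_age(p, labs$collection_date, registry$reference_date)
  labs$egfr <- compute_egfr_mdrd(
    labs$creatinine_mg_dl, age, p$sex, p$race == "black", coefficient
  )
  registry$labs <- labs
  registry
}

# Age in fractional years at `dates`; falls back to age_years at the
# reference date when birth_date is absent.
patient_age <- function(patients, dates, reference_date) {
  if ("birth_date" %in% names(patients) && !all(is.na(patients$birth_date))) {
    as.numeric(dates - patients$birth_date) / 365.25
  } else {
    patients$age_years + as.numeric(dates - reference_date) / 365.25
  }
}

#' Select the index and prior eGFR pair for every patient
#'
#' The index eGFR is the most recent value inside the lookback window ending
#' at the reference date; the prior eGFR is the most recent value dated at
#' least `min_gap_days` before the index date (still inside the lookback).
#' Same-day duplicates are resolved to the lowest eGFR (the conservative
#' choice when screening for advanced CKD). Patients with no qualifying
#' prior value get `NA` in the prior columns; patients with no lab in the
#' window are absent from the result.
#'
#' @param registry An `ehr_registry` whose labs carry `egfr` (see
#'   [add_egfr()]; computed on the fly when missing).
#' @param lookback_days Window length ending at the reference date,
#'   default 365 (both endpoints included).
#' @param min_gap_days Minimum index-to-prior separation, default 90.
#' @return Tibble with `patient_id`, `index_egfr`, `index_date`,
#'   `prior_egfr`, `prior_date`, `gap_days`.
#' @export
select_egfr_pairs <- function(registry, lookback_days = 365, min_gap_days = 90) {
  stopifnot(inherits(registry, "ehr_registry"))
  if (!"egfr" %in% names(registry$labs)) {
    registry <- add_egfr(registry)
  }
  ref <- registry$reference_date
  labs <- registry$labs
  labs <- labs[labs$collection_date >= ref - lookback_days &
    labs$collection_date <= ref, , drop = FALSE]
  if (nrow(labs) == 0) {
    return(tibble(
      patient_id = character(), index_egfr = numeric(),
      index_date = as.Date(character()), prior_egfr = numeric(),
      prior_date = as.Date(character()), gap_days = numeric()
    ))
  }
  labs <- arrange(labs, .data$patient_id, .data$collection_date, .data$egfr)
  index <- labs |>
    group_by(.data$patient_id) |>
    summarise(
      index_date = max(.data$collection_date),
      index_egfr = min(.data$egfr[.data$collection_date == index_date]),
      .groups = "drop"
    )
  prior_labs <- labs |>
    left_join(index, by = "patient_id") |>
    filter(.data$collection_date <= .data$index_date - min_gap_days)
  prior <- if (nrow(prior_labs) == 0) {
    tibble(
      patient_id = character(), prior_date = as.Date(character()),
      prior_egfr = numeric()
    )
  } else {
    prior_labs |>
      group_by(.data$patient_id) |>
      summarise(
        prior_date = max(.data$collection_date),
        prior_egfr = min(.data$egfr[.data$collection_date == prior_date]),
        .groups = "drop"
      )
  }
  out <- left_join(index, prior, by = "patient_id")
  out$gap_days <- as.numeric(out$index_date - out$prior_date)
  out[c(
    "patient_id", "index_egfr", "index_date",
    "prior_egfr", "prior_date", "gap_days"
  )]
}
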