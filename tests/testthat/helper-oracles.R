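# Independent oracles and tiny fixtures shared across the suite.

ref_date <- as.Date("2021-04-15")

# Closed-form Wilson score interval (independent of prop.test).
wilson_oracle <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(centre - half, centre + half) / (1 + z^2 / n)
}

# Brute-force 2x2 cross-classification by per-patient loop.
confusion_oracle <- function(pred, ref, universe) {
  tp <- fp <- fn <- tn <- 0L
  for (id in universe) {
    p <- id %in% pred
    r <- id %in% ref
    if (p && r) tp <- tp + 1L else if (p) fp <- fp + 1L else if (r) fn <- fn + 1L else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Brute-force follow-up summary for one group of patients.
followup_oracle <- function(ids, labs, pairs, ref, horizon = 180, thr = 30) {
  n_sub <- n_any <- n_cur <- 0L
  for (id in ids) {
    idx <- pairs$index_date[pairs$patient_id == id]
    if (length(idx) == 0 || is.na(idx)) next
    fu <- labs[labs$patient_id == id &
      labs$collection_date > idx &
      labs$collection_date <= ref + horizon, , drop = FALSE]
    if (nrow(fu) == 0) next
    n_sub <- n_sub + 1L
    if (any(fu$egfr >= thr)) n_any <- n_any + 1L
    last <- max(fu$collection_date)
    cur <- min(fu$egfr[fu$collection_date == last])
    if (cur >= thr) n_cur <- n_cur + 1L
  }
  list(n_subsequent = n_sub, n_any_ge30 = n_any, n_current_ge30 = n_cur)
}

# Hand-transcribed tier oracle over every combination of
# index band x prior band x code x AKI (48 cells).
tier_oracle_grid <- function() {
  idx <- c(lo = 25, mid = 45, hi = 75)
  pri <- c(lo = 25, mid = 45, hi = 75, absent = NA)
  grid <- expand.grid(
    index_band = names(idx), prior_band = names(pri),
    code = c(FALSE, TRUE), aki = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  grid$index <- idx[grid$index_band]
  grid$prior <- pri[grid$prior_band]
  grid$expected <- with(grid, ifelse(
    index_band == "lo" & prior_band == "lo", "high",
    ifelse(
      index_band == "lo" & prior_band == "mid" & !aki, "intermediate",
      ifelse(
        index_band == "lo" & prior_band == "mid" & aki, "excluded_aki",
        ifelse(
          index_band == "mid" & prior_band == "lo" & code, "intermediate",
          ifelse(
            index_band %in% c("mid", "hi") & prior_band %in% c("mid", "hi") & code, "low",
            "unclassified"
          )
        )
      )
    )
  ))
  grid
}

# One-patient registry whose index eGFR equals `egfr` exactly.
make_boundary_registry <- function(egfr) {
  patients <- tibble::tibble(
    patient_id = "pb", age_years = 70, sex = "male",
    race = "white", enrolled = TRUE
  )
  labs <- tibble::tibble(
    patient_id = "pb", collection_date = ref_date - 10,
    creatinine_mg_dl = ckdtier::invert_mdrd(egfr, 70 - 10 / 365.25, "male", FALSE),
    # pre-filled so the boundary value is exact (no float round-trip)
    egfr = egfr
  )
  empty <- tibble::tibble(
    patient_id = character(), event_date = as.Date(character()),
    system = character(), code = character()
  )
  ckdtier::ehr_registry(patients, labs, empty, empty, ref_date)
}

# Hand-built four-patient registry exercising both cohort arms, the
# dialysis exclusion and a code-only member.
tiny_registry <- function() {
  patients <- tibble::tibble(
    patient_id = c("p1", "p2", "p3", "p4"),
    birth_date = ref_date - round(c(70, 75, 80, 65) * 365.25),
    sex = c("male", "female", "male", "male"),
    race = c("white", "black", "white", "other"),
    enrolled = TRUE
  )
  # p1: index/prior both low (high tier); p2: index <30, prior mid;
  # p3: code-only, normal eGFR; p4: dialysis-coded.
  labs <- tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p2", "p3", "p3", "p4"),
    collection_date = ref_date - c(10, 200, 5, 150, 20, 180, 15),
    creatinine_mg_dl = NA_real_
  )
  target <- c(25, 26, 28, 45, 70, 72, 9)
  age <- as.numeric(labs$collection_date -
    patients$birth_date[match(labs$patient_id, patients$patient_id)]) / 365.25
  sex <- patients$sex[match(labs$patient_id, patients$patient_id)]
  race <- patients$race[match(labs$patient_id, patients$patient_id)]
  labs$creatinine_mg_dl <- ckdtier::invert_mdrd(target, age, sex, race == "black")
  diagnoses <- tibble::tibble(
    patient_id = c("p3", "p4"),
    event_date = ref_date - c(30, 40),
    system = "ICD10",
    code = c("N18.4", "Z99.2")
  )
  procedures <- tibble::tibble(
    patient_id = "p4", event_date = ref_date - 40,
    system = "CPT", code = "90935"
  )
  ckdtier::ehr_registry(patients, labs, diagnoses, procedures, ref_date)
}
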