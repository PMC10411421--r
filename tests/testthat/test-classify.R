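oracle_grid <- tier_oracle_grid()

test_that("classify_tier matches the hand-coded oracle on all 48 cells", {
  got <- classify_tier(
    oracle_grid$index, oracle_grid$prior,
    oracle_grid$code, oracle_grid$aki,
    detail = TRUE
  )
  expect_equal(as.character(got$tier), oracle_grid$expected)
  # subgroup bookkeeping: 1 for the falling pattern, 2 for the rising one
  is_int <- oracle_grid$expected == "intermediate"
  expect_true(all(!is.na(got$subgroup[is_int])))
  expect_true(all(is.na(got$subgroup[!is_int])))
  expect_equal(
    got$subgroup[is_int],
    ifelse(oracle_grid$index_band[is_int] == "lo", 1L, 2L)
  )
})

test_that("tier examples from the definition behave as printed", {
  expect_equal(as.character(classify_tier(25, 28, FALSE, FALSE)), "high")
  expect_equal(as.character(classify_tier(25, 28, TRUE, TRUE)), "high")
  expect_equal(as.character(classify_tier(25, 45, TRUE, FALSE)), "intermediate")
  expect_equal(as.character(classify_tier(25, 45, TRUE, TRUE)), "excluded_aki")
  expect_equal(as.character(classify_tier(40, 25, TRUE, FALSE)), "intermediate")
  expect_equal(as.character(classify_tier(40, 45, TRUE, FALSE)), "low")
  expect_equal(as.character(classify_tier(40, 45, FALSE, FALSE)), "unclassified")
  expect_equal(as.character(classify_tier(25, NA, TRUE, FALSE)), "unclassified")
  expect_error(classify_tier(NA, 28, TRUE, FALSE), "index_egfr")
})

test_that("thresholds compare at full precision with strict/non-strict bounds as defined", {
  eps <- 1e-9
  expect_equal(as.character(classify_tier(30 - eps, 30 - eps, FALSE, FALSE)), "high")
  expect_equal(as.character(classify_tier(30, 30 - eps, TRUE, FALSE)), "intermediate")
  expect_equal(as.character(classify_tier(30 - eps, 30, FALSE, FALSE)), "intermediate")
  expect_equal(as.character(classify_tier(30, 30, TRUE, FALSE)), "low")
  expect_equal(as.character(classify_tier(60, 25, TRUE, FALSE)), "unclassified")
  expect_equal(as.character(classify_tier(30 - eps, 60, FALSE, FALSE)), "unclassified")
})

test_that("classify_tier is pure and tiers partition the input space", {
  set.seed(41)
  idx <- runif(500, 5, 90)
  pri <- ifelse(runif(500) < 0.1, NA, runif(500, 5, 90))
  code <- runif(500) < 0.5
  aki <- runif(500) < 0.2
  a <- classify_tier(idx, pri, code, aki)
  b <- classify_tier(idx, pri, code, aki)
  expect_identical(a, b)
  expect_false(any(is.na(a)))
})

test_that("comparator phenotypes follow their definitions on the tiny registry", {
  reg <- tiny_registry()
  cohort <- build_source_cohort(reg)
  icd <- apply_phenotype(cohort, reg, "icd_only")
  single <- apply_phenotype(cohort, reg, "single_egfr")
  two <- apply_phenotype(cohort, reg, "two_egfr")
  # p3: code only, index eGFR 70
  expect_true(icd$label[icd$patient_id == "p3"])
  expect_false(single$label[single$patient_id == "p3"])
  # p2: index 28, prior 45 -> positive under both eGFR phenotypes
  expect_true(single$label[single$patient_id == "p2"])
  expect_true(two$label[two$patient_id == "p2"])
  expect_error(apply_phenotype(cohort, reg, "nope"), "phenotype")
})

test_that("index <30 with prior >=60 splits single- and two-eGFR phenotypes", {
  reg <- tiny_registry()
  # rewrite p2's prior lab to eGFR 65
  reg2 <- reg
  i <- which(reg2$labs$patient_id == "p2" & reg2$labs$collection_date == ref_date - 150)
  age <- as.numeric(reg2$labs$collection_date[i] - reg2$patients$birth_date[2]) / 365.25
  reg2$labs$creatinine_mg_dl[i] <- invert_mdrd(65, age, "female", TRUE)
  cohort <- build_source_cohort(reg2)
  single <- apply_phenotype(cohort, reg2, "single_egfr")
  two <- apply_phenotype(cohort, reg2, "two_egfr")
  expect_true(single$label[single$patient_id == "p2"])
  expect_false(two$label[two$patient_id == "p2"])
  # and the tier is the residual group
  a <- assign_tiers(cohort, reg2)
  expect_equal(as.character(a$tier[a$patient_id == "p2"]), "unclassified")
})

test_that("missing prior keeps a patient positive under single_egfr but NA under two_egfr", {
  reg <- tiny_registry()
  reg2 <- reg
  reg2$labs <- reg2$labs[!(reg2$labs$patient_id == "p2" &
    reg2$labs$collection_date == ref_date - 150), ]
  cohort <- build_source_cohort(reg2)
  single <- apply_phenotype(cohort, reg2, "single_egfr")
  two <- apply_phenotype(cohort, reg2, "two_egfr")
  expect_true(single$label[single$patient_id == "p2"])
  expect_true(is.na(two$label[two$patient_id == "p2"]))
})

test_that("tier/phenotype set relations hold on synthetic cohorts", {
  reg <- add_egfr(generate_registry(sim_config(n_patients = 3000), seed = 12))
  cohort <- build_source_cohort(reg)
  a <- assign_tiers(cohort, reg)
  two <- apply_phenotype(cohort, reg, "two_egfr")
  icd <- apply_phenotype(cohort, reg, "icd_only")
  high_ids <- a$patient_id[a$tier == "high"]
  two_pos <- two$patient_id[two$label %in% TRUE]
  expect_true(all(high_ids %in% two_pos))
  # icd positives with both eGFR values >= 30 are exactly the low tier
  both_ge30 <- a$patient_id[!is.na(a$index_egfr) & !is.na(a$prior_egfr) &
    a$index_egfr >= 30 & a$prior_egfr >= 30]
  icd_pos <- icd$patient_id[icd$label %in% TRUE]
  expect_setequal(intersect(icd_pos, both_ge30), a$patient_id[a$tier == "low"])
})

test_that("AKI flag is anchored to the 90 days before the index date", {
  reg <- tiny_registry()
  add_aki <- function(offset_from_index) {
    r <- reg
    idx_date <- ref_date - 5 # p2's index lab
    r$diagnoses <- dplyr::bind_rows(
      r$diagnoses,
      tibble::tibble(
        patient_id = "p2", event_date = idx_date - offset_from_index,
        system = "ICD10", code = "N17.0"
      )
    )
    cohort <- build_source_cohort(r)
    assign_tiers(cohort, r)
  }
  # p2 is index 28 / prior 45: subgroup 1 without AKI, carved out with it
  a_in <- add_aki(90)
  expect_equal(as.character(a_in$tier[a_in$patient_id == "p2"]), "excluded_aki")
  a_edge <- add_aki(0)
  expect_equal(as.character(a_edge$tier[a_edge$patient_id == "p2"]), "excluded_aki")
  a_out <- add_aki(91)
  expect_equal(as.character(a_out$tier[a_out$patient_id == "p2"]), "intermediate")
})
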