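# Registry with controllable follow-up eGFRs for a single patient whose
# index lab sits at the reference date.
make_fu_registry <- function(fu_offsets, fu_egfrs, index_egfr = 25, prior_egfr = 28) {
  patients <- tibble::tibble(
    patient_id = "p1", age_years = 70, sex = "male",
    race = "white", enrolled = TRUE
  )
  offsets <- c(0, 120, -fu_offsets) # negative offset = after reference date
  egfrs <- c(index_egfr, prior_egfr, fu_egfrs)
  labs <- tibble::tibble(
    patient_id = "p1",
    collection_date = ref_date - offsets,
    creatinine_mg_dl = invert_mdrd(egfrs, 70 - offsets / 365.25, "male", FALSE)
  )
  empty <- tibble::tibble(
    patient_id = character(), event_date = as.Date(character()),
    system = character(), code = character()
  )
  ehr_registry(patients, labs, empty, empty, ref_date)
}

test_that("any/current follow-up definitions match hand evaluation", {
  reg <- make_fu_registry(c(30, 90, 150), c(28, 35, 27))
  pairs <- select_egfr_pairs(reg)
  fu <- followup_stats(list(g = "p1"), reg, pairs)
  expect_equal(fu$n_subsequent, 1L)
  expect_equal(fu$n_any_ge30, 1L) # the 35 at day +90
  expect_equal(fu$n_current_ge30, 0L) # latest is 27
  expect_equal(fu$pct_remaining, 100)
})

test_that("current uses the latest value within the horizon only", {
  # latest in-horizon value is 35 even though a later out-of-horizon lab is 20
  reg <- make_fu_registry(c(60, 170), c(27, 35))
  fu <- followup_stats(list(g = "p1"), reg, select_egfr_pairs(reg))
  expect_equal(fu$n_current_ge30, 1L)
  expect_equal(fu$pct_remaining, 0)
  fu90 <- followup_stats(list(g = "p1"), reg, select_egfr_pairs(reg), horizon_days = 90)
  expect_equal(fu90$n_current_ge30, 0L) # only the day-60 value (27) remains
})

test_that("patients without follow-up labs leave pct_remaining undefined", {
  reg <- make_fu_registry(integer(), numeric())
  fu <- followup_stats(list(g = "p1"), reg, select_egfr_pairs(reg))
  expect_equal(fu$n_subsequent, 0L)
  expect_true(is.na(fu$pct_remaining))
  expect_warning(
    followup_stats(list(g = "p1", empty = character()), reg, select_egfr_pairs(reg)),
    "empty"
  )
})

test_that("denominator conventions differ between any and current", {
  # 3 patients: two with follow-up, one without
  regs <- list(
    make_fu_registry(c(30), c(40)), # any>=30 yes, current>=30 yes
    make_fu_registry(c(30, 60), c(40, 20)) # any yes, current no
  )
  # merge into one registry with distinct ids
  pat <- dplyr::bind_rows(lapply(1:3, function(i) {
    tibble::tibble(
      patient_id = paste0("p", i), age_years = 70, sex = "male",
      race = "white", enrolled = TRUE
    )
  }))
  labs <- dplyr::bind_rows(
    dplyr::mutate(regs[[1]]$labs, patient_id = "p1"),
    dplyr::mutate(regs[[2]]$labs, patient_id = "p2"),
    tibble::tibble(
      patient_id = "p3", collection_date = ref_date - c(0, 120),
      creatinine_mg_dl = invert_mdrd(c(25, 28), 70, "male", FALSE)
    )
  )
  empty <- tibble::tibble(
    patient_id = character(), event_date = as.Date(character()),
    system = character(), code = character()
  )
  reg <- ehr_registry(pat, labs, empty, empty, ref_date)
  fu <- followup_stats(list(g = c("p1", "p2", "p3")), reg, select_egfr_pairs(reg))
  expect_equal(fu$n_group, 3L)
  expect_equal(fu$n_subsequent, 2L)
  expect_equal(fu$pct_any_ge30, 100 * 2 / 3) # over the whole group
  expect_equal(fu$pct_current_ge30, 100 * 1 / 2) # over those with follow-up
  expect_equal(fu$pct_remaining, 50)
  expect_true(fu$n_subsequent <= fu$n_group)
  expect_true(fu$n_current_ge30 <= fu$n_subsequent)
  expect_true(fu$n_any_ge30 <= fu$n_group)
})

test_that("followup_stats agrees with per-patient brute force on synthetic cohorts", {
  for (seed in c(4, 29)) {
    reg <- add_egfr(generate_registry(sim_config(n_patients = 500), seed = seed))
    cohort <- build_source_cohort(reg)
    a <- assign_tiers(cohort, reg)
    groups <- split(a$patient_id, as.character(a$tier), drop = TRUE)
    fu <- suppressWarnings(followup_stats(groups, reg, cohort$pairs))
    for (g in fu$group) {
      want <- followup_oracle(groups[[g]], reg$labs, cohort$pairs, ref_date)
      got <- fu[fu$group == g, ]
      expect_equal(got$n_subsequent, want$n_subsequent, label = g)
      expect_equal(got$n_any_ge30, want$n_any_ge30, label = g)
      expect_equal(got$n_current_ge30, want$n_current_ge30, label = g)
    }
  }
})

test_that("gap statistics are the sample mean/SD of index-prior gaps", {
  pairs <- tibble::tibble(
    patient_id = c("a", "b", "c"),
    index_egfr = 25, index_date = ref_date,
    prior_egfr = c(28, 27, NA),
    prior_date = c(ref_date - 100, ref_date - 200, as.Date(NA)),
    gap_days = c(100, 200, NA)
  )
  gs <- gap_statistics(list(all = c("a", "b", "c"), single = "a"), pairs)
  expect_equal(gs$n_pairs, c(2L, 1L))
  expect_equal(gs$mean_gap_days[1], 150)
  expect_equal(gs$sd_gap_days[1], sd(c(100, 200))) # 70.7107
  expect_equal(round(gs$sd_gap_days[1], 2), 70.71)
  expect_true(is.na(gs$sd_gap_days[2])) # single pair: SD undefined
})

test_that("selected pairs always satisfy the 90-day minimum gap", {
  reg <- add_egfr(generate_registry(sim_config(n_patients = 400), seed = 10))
  pairs <- select_egfr_pairs(reg)
  expect_true(all(pairs$gap_days >= 90, na.rm = TRUE))
})

test_that("cumulative prevalence accumulates monthly qualifiers over a fixed denominator", {
  reg <- add_egfr(generate_registry(sim_config(n_patients = 2500), seed = 15))
  cum <- cumulative_prevalence(reg)
  expect_equal(cum$estimate$denominator, length(creatinine_tested_users(reg)))
  expect_equal(cum$estimate$numerator, length(cum$ids))
  # cumulative counts are monotone non-decreasing
  expect_true(all(diff(cum$per_snapshot$n_cumulative) >= 0))
  # the cumulative set contains the initial high/intermediate qualifiers
  a <- assign_tiers(build_source_cohort(reg), reg)
  init <- a$patient_id[a$tier %in% c("high", "intermediate")]
  expect_true(all(init %in% cum$ids))
})
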