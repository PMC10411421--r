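test_that("MDRD equation reproduces direct evaluation and its factor ratios", {
  # 175 * 2.5^-1.154 * 60^-0.203 evaluated independently
  expect_equal(compute_egfr_mdrd(2.5, 60, "male", FALSE),
    175 * 2.5^-1.154 * 60^-0.203,
    tolerance = 1e-12
  )
  expect_equal(compute_egfr_mdrd(2.5, 60, "male", FALSE), 26.4758904, tolerance = 1e-6)
  f <- compute_egfr_mdrd(1.8, 70, "female", FALSE)
  m <- compute_egfr_mdrd(1.8, 70, "male", FALSE)
  expect_equal(f / m, 0.742, tolerance = 1e-12)
  b <- compute_egfr_mdrd(1.8, 70, "male", TRUE)
  expect_equal(b / m, 1.212, tolerance = 1e-12)
  # configurable leading coefficient scales linearly
  expect_equal(
    compute_egfr_mdrd(1.8, 70, "male", FALSE, coefficient = 186) / m,
    186 / 175,
    tolerance = 1e-12
  )
})

test_that("MDRD is strictly decreasing in creatinine and age", {
  set.seed(21)
  for (i in 1:50) {
    scr <- sort(runif(2, 0.4, 8))
    age <- runif(1, 20, 95)
    sex <- sample(c("male", "female"), 1)
    blk <- sample(c(TRUE, FALSE), 1)
    expect_gt(
      compute_egfr_mdrd(scr[1], age, sex, blk),
      compute_egfr_mdrd(scr[2], age, sex, blk)
    )
    ages <- sort(runif(2, 20, 95))
    expect_gt(
      compute_egfr_mdrd(scr[1], ages[1], sex, blk),
      compute_egfr_mdrd(scr[1], ages[2], sex, blk)
    )
  }
})

test_that("invert_mdrd is the exact algebraic inverse", {
  scr <- invert_mdrd(29.9, 75, "male", FALSE)
  expect_equal(compute_egfr_mdrd(scr, 75, "male", FALSE), 29.9, tolerance = 1e-9)
  # power-law scaling: doubling the target scales creatinine by 2^(-1/1.154)
  expect_equal(
    invert_mdrd(59.8, 75, "male", FALSE) / scr,
    2^(-1 / 1.154),
    tolerance = 1e-12
  )
  # grid sweep
  set.seed(33)
  g <- runif(100, 5, 120)
  age <- runif(100, 20, 95)
  sex <- sample(c("male", "female"), 100, replace = TRUE)
  blk <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  back <- compute_egfr_mdrd(invert_mdrd(g, age, sex, blk), age, sex, blk)
  expect_lt(max(abs(back - g) / g), 1e-9)
})

test_that("domain errors are raised for non-positive inputs", {
  expect_error(compute_egfr_mdrd(0, 60, "male", FALSE), "positive")
  expect_error(compute_egfr_mdrd(1.2, -1, "male", FALSE), "positive")
  expect_error(compute_egfr_mdrd(1.2, 60, "M", FALSE), "sex")
  expect_error(invert_mdrd(0, 60, "male", FALSE), "positive")
})

make_pair_registry <- function(offsets, egfrs) {
  patients <- tibble::tibble(
    patient_id = "p1", age_years = 70, sex = "male",
    race = "white", enrolled = TRUE
  )
  labs <- tibble::tibble(
    patient_id = "p1",
    collection_date = ref_date - offsets,
    # invert at the age add_egfr will use (age at collection date)
    creatinine_mg_dl = invert_mdrd(egfrs, 70 - offsets / 365.25, "male", FALSE)
  )
  empty <- tibble::tibble(
    patient_id = character(), event_date = as.Date(character()),
    system = character(), code = character()
  )
  ehr_registry(patients, labs, empty, empty, ref_date)
}

test_that("index/prior pair selection follows the lookback and gap rules", {
  # index = latest, prior = most recent >= 90 days earlier
  pairs <- select_egfr_pairs(make_pair_registry(c(200, 10), c(40, 25)))
  expect_equal(pairs$index_egfr, 25, tolerance = 1e-6)
  expect_equal(pairs$prior_egfr, 40, tolerance = 1e-6)
  expect_equal(pairs$gap_days, 190)

  # single lab: prior absent
  pairs <- select_egfr_pairs(make_pair_registry(10, 25))
  expect_true(is.na(pairs$prior_egfr))

  # 85-day gap is not enough
  pairs <- select_egfr_pairs(make_pair_registry(c(95, 10), c(40, 25)))
  expect_true(is.na(pairs$prior_egfr))
  # exactly 90 days qualifies
  pairs <- select_egfr_pairs(make_pair_registry(c(100, 10), c(40, 25)))
  expect_equal(pairs$prior_egfr, 40, tolerance = 1e-6)

  # labs outside the 365-day lookback are invisible
  pairs <- select_egfr_pairs(make_pair_registry(c(366, 10), c(40, 25)))
  expect_true(is.na(pairs$prior_egfr))
  expect_equal(nrow(select_egfr_pairs(make_pair_registry(366, 40))), 0)

  # the most recent qualifying prior wins, not the oldest
  pairs <- select_egfr_pairs(make_pair_registry(c(300, 150, 10), c(55, 40, 25)))
  expect_equal(pairs$prior_egfr, 40, tolerance = 1e-6)
})

test_that("same-day duplicates resolve to the lowest eGFR and order does not matter", {
  reg <- make_pair_registry(c(10, 10, 150), c(32, 28, 45))
  pairs <- select_egfr_pairs(reg)
  expect_equal(pairs$index_egfr, 28, tolerance = 1e-6)
  reg2 <- reg
  reg2$labs <- reg2$labs[c(3, 1, 2), ]
  expect_equal(as.data.frame(select_egfr_pairs(reg2)), as.data.frame(pairs))
})

test_that("prior is never within 90 days of the index across random registries", {
  set.seed(9)
  for (i in 1:25) {
    k <- sample(2:8, 1)
    reg <- make_pair_registry(sample(0:400, k), runif(k, 10, 90))
    pairs <- select_egfr_pairs(reg)
    if (nrow(pairs) && !is.na(pairs$prior_date)) {
      expect_gte(pairs$gap_days, 90)
    }
    # permutation invariance
    reg2 <- reg
    reg2$labs <- reg2$labs[sample(nrow(reg2$labs)), ]
    expect_equal(as.data.frame(select_egfr_pairs(reg2)), as.data.frame(pairs))
  }
})

test_that("add_egfr uses age at the collection date", {
  reg <- tiny_registry()
  reg <- add_egfr(reg)
  p1 <- reg$labs[reg$labs$patient_id == "p1", ]
  age <- as.numeric(p1$collection_date - reg$patients$birth_date[1]) / 365.25
  expect_equal(p1$egfr,
    compute_egfr_mdrd(p1$creatinine_mg_dl, age, "male", FALSE),
    tolerance = 1e-12
  )
  # tiny_registry targets were built by inversion, so eGFR recovers them
  expect_equal(p1$egfr, c(25, 26), tolerance = 1e-9)
})
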