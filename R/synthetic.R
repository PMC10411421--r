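#' Configuration for the synthetic EHR generator
#'
#' Bundles and validates every knob of [generate_registry()]. Defaults
#' describe a regional health system of mostly elderly, predominantly male
#' patients in which roughly 1.9% of creatinine-tested users have advanced
#' CKD, split across the high/intermediate/low tiers in roughly the
#' 53/27/18 proportions seen in such cohorts.
#'
#' @param n_patients Number of patients.
#' @param reference_date Extraction date of the simulated registry.
#' @param frac_tested Probability that a non-CKD patient has any creatinine
#'   lab in the 12-month lookback (CKD-group and dialysis patients are
#'   always tested; sicker patients get measured).
#' @param weights Named mixture weights over
#'   `c(high, intermediate, low, nonckd, dialysis)`; normalised to sum
#'   to 1.
#' @param intermediate_sub2_frac Fraction of intermediate-risk patients
#'   simulated with the rising pattern (index in \[30,60), prior < 30).
#' @param egfr_mean,egfr_sd Named per-group baseline (index-anchor) eGFR
#'   mean and SD, ml/min/1.73 m^2.
#' @param drift_per_month Named per-group true-eGFR drift after the index
#'   date, ml/min/1.73 m^2 per 30 days (negative = progression).
#' @param followup_rate Named per-group expected number of follow-up labs
#'   per year after the reference date.
#' @param history_rate Expected number of extra historical labs (before the
#'   prior anchor) per patient.
#' @param noise_sd SD of the multiplicative lognormal noise on serum
#'   creatinine (0.15 = roughly 15% coefficient of variation, a typical
#'   physiologic + assay variability).
#' @param coding_sensitivity Probability that a high-risk or
#'   intermediate-subgroup-1 patient carries an advanced-CKD diagnosis code
#'   (subgroup-2 and low-risk patients carry one by construction, as their
#'   definitions require it).
#' @param coding_fp_rate Probability that a non-CKD patient carries a
#'   spurious advanced-CKD code.
#' @param aki_rate Probability that an intermediate-subgroup-1 patient has
#'   an AKI (N17) diagnosis within 90 days before the index date.
#' @param aki_drop Fractional transient true-eGFR drop applied to labs in
#'   the 30 days after an AKI event.
#' @param dialysis_miscode_rate Probability that a dialysis patient carries
#'   no dialysis codes (and so can leak into a code-based screen).
#' @param age_mean,age_sd,pct_male,pct_black,pct_white Demographic
#'   marginals (age truncated to \[20, 105\] years).
#' @param horizon_days Follow-up horizon simulated after the reference
#'   date.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 5000,
                       reference_date = as.Date("2021-04-15"),
                       frac_tested = 0.70,
                       weights = c(
                         high = 0.0100, intermediate = 0.0052,
                         low = 0.0034, nonckd = 0.9784, dialysis = 0.0030
                       ),
                       intermediate_sub2_frac = 0.20,
                       egfr_mean = c(
                         high = 20.3, intermediate = 27.4, low = 42.1,
                         nonckd = 75, dialysis = 8
                       ),
                       egfr_sd = c(
                         high = 6.6, intermediate = 5.6, low = 16.6,
                         nonckd = 15, dialysis = 3
                       ),
                       drift_per_month = c(
                         high = -0.2, intermediate = 0, low = 0,
                         nonckd = 0, dialysis = -0.5
                       ),
                       followup_rate = c(
                         high = 1.8, intermediate = 1.4, low = 1.7,
                         nonckd = 1.0, dialysis = 2.0
                       ),
                       history_rate = 1.0,
                       noise_sd = 0.15,
                       coding_sensitivity = 0.55,
                       coding_fp_rate = 0.001,
                       aki_rate = 0.10,
                       aki_drop = 0.30,
                       dialysis_miscode_rate = 0.112,
                       age_mean = 75.3, age_sd = 11.1,
                       pct_male = 0.958,
                       pct_black = 0.219, pct_white = 0.678,
                       horizon_days = 180) {
  groups <- c("high", "intermediate", "low", "nonckd", "dialysis")
  cfg <- as.list(environment())
  if (!setequal(names(cfg$weights), groups)) {
    abort(sprintf("`weights` must be named over: %s", paste(groups, collapse = ", ")))
  }
  if (any(cfg$weights < 0) || sum(cfg$weights) <= 0) {
    abort("`weights` must be non-negative with a positive sum.")
  }
  cfg$weights <- cfg$weights[groups] / sum(cfg$weights)
  for (nm in c("egfr_mean", "egfr_sd", "drift_per_month", "followup_rate")) {
    if (!all(groups %in% names(cfg[[nm]]))) {
      abort(sprintf("`%s` must be named over all groups.", nm))
    }
    cfg[[nm]] <- cfg[[nm]][groups]
  }
  if (any(cfg$egfr_sd < 0) || cfg$noise_sd < 0 || cfg$history_rate < 0 ||
    any(cfg$followup_rate < 0)) {
    abort("Rates and standard deviations must be non-negative.")
  }
  for (nm in c(
    "frac_tested", "intermediate_sub2_frac", "coding_sensitivity",
    "coding_fp_rate", "aki_rate", "aki_drop", "dialysis_miscode_rate",
    "pct_male", "pct_black", "pct_white"
  )) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      abort(sprintf("`%s` must be a probability in [0, 1].", nm))
    }
  }
  if (cfg$pct_black + cfg$pct_white > 1) {
    abort("`pct_black + pct_white` must not exceed 1.")
  }
  cfg$reference_date <- assert_scalar_date(reference_date, "reference_date")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic four-table EHR registry
#'
#' Simulates, per patient: a group label from the configured mixture; a
#' true eGFR trajectory anchored at an index value (and, for CKD groups, a
#' prior value at least 90 days earlier) with per-group drift after the
#' index date and transient AKI dips; serum creatinine derived from the
#' trajectory by inverting the MDRD equation for the patient's
#' demographics, with multiplicative lognormal noise; and diagnosis/
#' procedure codes per the coding model (advanced-CKD codes with the
#' configured sensitivity and false-positive rate, dialysis codes unless
#' miscoded, AKI codes for the carved-out intermediate patients).
#'
#' The output is fully reproducible from `seed` and carries a ground-truth
#' table retrievable with [truth_table()].
#'
#' @param config A [sim_config()].
#' @param seed Integer seed fixing the whole registry.
#' @return An `ehr_registry` with a `truth` attribute.
#' @export
generate_registry <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, globalenv()),
    add = TRUE
  )
  set.seed(as.integer(seed))
  n <- config$n_patients
  ref <- config$reference_date
  groups <- names(config$weights)

  ids <- sprintf("P%06d", seq_len(n))
  group <- sample(groups, n, replace = TRUE, prob = config$weights)
  age <- rtruncnorm(n, config$age_mean, config$age_sd, 20, 105)
  sex <- ifelse(runif(n) < config$pct_male, "male", "female")
  race <- sample(c("black", "white", "other"), n,
    replace = TRUE,
    prob = c(
      config$pct_black, config$pct_white,
      1 - config$pct_black - config$pct_white
    )
  )
  birth_date <- ref - round(age * 365.25)
  patients <- tibble(
    patient_id = ids, birth_date = birth_date, sex = sex,
    race = race, enrolled = TRUE
  )

  is_ckd <- group %in% c("high", "intermediate", "low")
  tested <- is_ckd | group == "dialysis" | runif(n) < config$frac_tested

  sub <- rep(NA_integer_, n)
  is_int <- group == "intermediate"
  sub[is_int] <- ifelse(runif(sum(is_int)) < config$intermediate_sub2_frac, 2L, 1L)

  # True eGFR anchors. Index anchor drawn from the group distribution
  # truncated to the band its tier definition requires; the prior anchor
  # sits in the complementary band for the intermediate patterns.
  mu <- config$egfr_mean[group]
  sg <- config$egfr_sd[group]
  index_true <- numeric(n)
  prior_true <- rep(NA_real_, n)
  for (g in groups) {
    i <- which(group == g)
    if (!length(i)) next
    if (g == "high") {
      index_true[i] <- rtruncnorm(length(i), mu[i[1]], sg[i[1]], 5, 29.5)
      prior_true[i] <- pmin(pmax(index_true[i] + rnorm(length(i), 0, 3), 5), 29.5)
    } else if (g == "low") {
      index_true[i] <- rtruncnorm(length(i), mu[i[1]], sg[i[1]], 30.5, 120)
      prior_true[i] <- pmax(index_true[i] + rnorm(length(i), 0, 4), 30.5)
    } else if (g == "nonckd") {
      index_true[i] <- rtruncnorm(length(i), mu[i[1]], sg[i[1]], 60.5, 150)
      prior_true[i] <- pmax(index_true[i] + rnorm(length(i), 0, 5), 60.5)
    } else if (g == "dialysis") {
      index_true[i] <- rtruncnorm(length(i), mu[i[1]], sg[i[1]], 3, 14.5)
      prior_true[i] <- pmin(pmax(index_true[i] + rnorm(length(i), 0, 2), 3), 25)
    }
  }
  i1 <- which(is_int & sub == 1L)
  if (length(i1)) {
    index_true[i1] <- rtruncnorm(length(i1), config$egfr_mean["intermediate"],
      config$egfr_sd["intermediate"],
      a = 12, b = 29.5
    )
    prior_true[i1] <- rtruncnorm(length(i1), 38, 8, 30.5, 59.5)
  }
  i2 <- which(is_int & sub == 2L)
  if (length(i2)) {
    index_true[i2] <- rtruncnorm(length(i2), 35, 5, 30.5, 59.5)
    prior_true[i2] <- rtruncnorm(length(i2), 25, 3, 12, 29.5)
  }

  # Anchor dates: index near the reference date, prior >= 90 days earlier,
  # both within the 12-month lookback.
  index_offset <- sample(0:27, n, replace = TRUE)
  index_date <- ref - index_offset
  gap <- 90 + floor(runif(n, 0, 240))
  prior_date <- index_date - gap

  # AKI carve-out: subgroup-1 patients only, coded 0-60 days before the
  # index date so the dip window never reaches the prior anchor.
  aki <- rep(FALSE, n)
  aki[i1] <- runif(length(i1)) < config$aki_rate
  aki_date <- rep(as.Date(NA), n)
  aki_date[aki] <- index_date[aki] - sample(0:60, sum(aki), replace = TRUE)

  # Coding model.
  has_adv_code <- rep(FALSE, n)
  need_code <- group == "low" | (is_int & sub == 2L)
  has_adv_code[need_code] <- TRUE
  sens_pool <- group == "high" | (is_int & sub == 1L) | group == "dialysis"
  has_adv_code[sens_pool] <- runif(sum(sens_pool)) < config$coding_sensitivity
  fp_pool <- group == "nonckd"
  has_adv_code[fp_pool] <- runif(sum(fp_pool)) < config$coding_fp_rate
  dialysis_coded <- group == "dialysis" & runif(n) >= config$dialysis_miscode_rate

  truth <- tibble(
    patient_id = ids, group = group,
    tier = ifelse(group == "nonckd", "none",
      ifelse(group == "dialysis", "dialysis",
        ifelse(aki, "excluded_aki", group)
      )
    ),
    subgroup = sub,
    index_true = index_true, prior_true = prior_true,
    index_date = index_date, prior_date = prior_date,
    tested = tested, has_adv_code = has_adv_code,
    aki = aki, dialysis_coded = dialysis_coded
  )

  # Assemble labs: per-patient anchor labs, historical labs before the
  # prior anchor, and follow-up labs after the reference date.
  date_rows <- vector("list", n)
  g_rows <- vector("list", n)
  who <- vector("list", n)
  drift <- config$drift_per_month[group]
  for (k in seq_len(n)) {
    if (!tested[k]) {
      next
    }
    dates <- c(index_date[k], prior_date[k])
    g_true <- c(index_true[k], prior_true[k])
    n_hist <- rpois(1, config$history_rate)
    if (n_hist > 0) {
      span <- as.numeric(prior_date[k] - (ref - 365))
      if (span > 1) {
        hd <- prior_date[k] - sample(seq_len(span - 1), min(n_hist, span - 1))
        dates <- c(dates, hd)
        g_true <- c(g_true, rep(prior_true[k], length(hd)))
      }
    }
    n_fu <- rpois(1, config$followup_rate[group[k]] * config$horizon_days / 365)
    if (n_fu > 0) {
      fd <- unique(ref + sample(seq_len(config$horizon_days), n_fu, replace = TRUE))
      g_fu <- index_true[k] + drift[k] * as.numeric(fd - index_date[k]) / 30
      dates <- c(dates, fd)
      g_true <- c(g_true, g_fu)
    }
    if (aki[k]) {
      dip <- dates >= aki_date[k] & dates <= aki_date[k] + 30
      g_true[dip] <- g_true[dip] * (1 - config$aki_drop)
    }
    date_rows[[k]] <- dates
    g_rows[[k]] <- pmax(g_true, 2)
    who[[k]] <- rep(k, length(dates))
  }
  j <- unlist(who)
  if (length(j) > 0) {
    all_dates <- as.Date(unlist(date_rows), origin = "1970-01-01")
    g_all <- unlist(g_rows)
    age_at <- as.numeric(all_dates - birth_date[j]) / 365.25
    scr <- invert_mdrd(g_all, age_at, sex[j], race[j] == "black")
    noise <- if (config$noise_sd > 0) exp(rnorm(length(j), 0, config$noise_sd)) else 1
    labs <- tibble(
      patient_id = ids[j], collection_date = all_dates,
      creatinine_mg_dl = scr * noise
    )
    labs <- arrange(labs, .data$patient_id, .data$collection_date)
  } else {
    labs <- tibble(
      patient_id = character(), collection_date = as.Date(character()),
      creatinine_mg_dl = numeric()
    )
  }

  # Coded events.
  code_date <- ref - sample(0:364, n, replace = TRUE)
  dx <- list()
  adv <- which(has_adv_code)
  if (length(adv)) {
    dx$adv <- tibble(
      patient_id = ids[adv], event_date = code_date[adv],
      system = "ICD10",
      code = sample(c("N18.4", "N18.5"), length(adv), replace = TRUE)
    )
  }
  ak <- which(aki)
  if (length(ak)) {
    dx$aki <- tibble(
      patient_id = ids[ak], event_date = aki_date[ak],
      system = "ICD10", code = "N17.9"
    )
  }
  dialysed <- which(dialysis_coded)
  px <- list()
  if (length(dialysed)) {
    dx$dial <- tibble(
      patient_id = ids[dialysed], event_date = code_date[dialysed],
      system = "ICD10", code = "Z99.2"
    )
    px$dial <- tibble(
      patient_id = ids[dialysed], event_date = code_date[dialysed],
      system = "CPT", code = "90935"
    )
  }
  empty_events <- tibble(
    patient_id = character(), event_date = as.Date(character()),
    system = character(), code = character()
  )
  diagnoses <- if (length(dx)) bind_rows(dx) else empty_events
  procedures <- if (length(px)) bind_rows(px) else empty_events

  reg <- ehr_registry(patients, labs, diagnoses, procedures,
    reference_date = ref, horizon_days = config$horizon_days
  )
  attr(reg, "truth") <- truth
  attr(reg, "sim_config") <- config
  reg
}

#' Ground-truth labels of a synthetic registry
#'
#' Returns the per-patient truth table attached by [generate_registry()]:
#' the simulated group and tier (including `excluded_aki`, `dialysis` and
#' `none`), the true index/prior eGFR anchors and dates, tested/coding/
#' miscoding flags. Used to score phenotype output against truth.
#'
#' @param registry A registry produced by [generate_registry()].
#' @return Tibble of ground-truth labels.
#' @export
truth_table <- function(registry) {
  truth <- attr(registry, "truth")
  if (is.null(truth)) {
    abort("This registry carries no ground truth (not produced by generate_registry()).")
  }
  truth
}
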