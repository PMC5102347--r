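test_that("generation is deterministic given parameters and seed", {
  p <- small_params(120)
  b1 <- simulate_cohort(p, seed = 7)
  b2 <- simulate_cohort(p, seed = 7)
  expect_identical(b1$patients, b2$patients)
  expect_identical(b1$inpatient, b2$inpatient)
  expect_identical(b1$outpatient, b2$outpatient)
  b3 <- simulate_cohort(p, seed = 8)
  expect_false(identical(b1$patients$stage, b3$patients$stage))
})

test_that("degenerate stage distribution yields a single-stage cohort", {
  p <- small_params(100, stage_probs = single_stage_probs("IA_IB"))
  pts <- generate_patients(p)
  expect_equal(nrow(pts), 100)
  expect_true(all(pts$stage == "IA_IB"))
})

test_that("stage frequencies converge to configured probabilities", {
  pts <- generate_patients(stagecost_params(n_patients = 4910), seed = 20)
  frac <- mean(pts$stage == "IA_IB")
  p0 <- 277 / 491
  se <- sqrt(p0 * (1 - p0) / 4910)
  expect_lt(abs(frac - p0), 3 * se)
})

test_that("missingness switches off cleanly and matches configured rates", {
  p0 <- small_params(400, missing_rates = list(histology = 0, grade = 0,
                                               imd = 0, bmi = 0))
  pts <- generate_patients(p0)
  expect_false(anyNA(pts$grade))
  expect_false(anyNA(pts$bmi))
  expect_false(anyNA(pts$histology))
  expect_false(anyNA(pts$imd_quintile))

  pts2 <- generate_patients(stagecost_params(n_patients = 5000), seed = 3)
  expect_lt(abs(mean(is.na(pts2$grade)) - 0.032),
            3 * sqrt(0.032 * 0.968 / 5000))
})

test_that("birth and death dates sit on the 15th of the month", {
  p <- small_params(250)
  pts <- generate_survival(generate_patients(p), p)
  expect_true(all(format(pts$birth_date, "%d") == "15"))
  dd <- pts$death_date[!is.na(pts$death_date)]
  # deaths in the diagnosis month are clamped to the diagnosis day
  dxm <- format(pts$diagnosis_date[!is.na(pts$death_date)], "%Y-%m")
  regular <- format(dd, "%Y-%m") != dxm
  expect_true(all(format(dd[regular], "%d") == "15"))
})

test_that("five-year survival calibration is recovered empirically", {
  p <- stagecost_params(n_patients = 8000,
                        stage_probs = single_stage_probs("IA_IB"))
  pts <- generate_survival(generate_patients(p, seed = 4), p, seed = 5)
  # fully observed at 5y given the long mortality window for most patients
  surv5 <- mean(is.na(pts$death_date_full) |
                  yrs(pts$diagnosis_date, pts$death_date_full) > 5)
  expect_lt(abs(surv5 - 0.94), 3 * sqrt(0.94 * 0.06 / 8000))
})

test_that("every episode belongs to a known patient and respects time bounds", {
  p <- small_params(300)
  b <- simulate_cohort(p, seed = 10)
  expect_true(all(b$inpatient$patient_id %in% b$patients$patient_id))
  expect_true(all(b$outpatient$patient_id %in% b$patients$patient_id))
  dx_ip <- b$patients$diagnosis_date[match(b$inpatient$patient_id,
                                           b$patients$patient_id)]
  dx_op <- b$patients$diagnosis_date[match(b$outpatient$patient_id,
                                           b$patients$patient_id)]
  expect_true(all(b$inpatient$admission_date >= dx_ip - 183))
  expect_true(all(b$outpatient$date >= dx_op - 183))
  expect_true(all(yrs(dx_ip, b$inpatient$admission_date) < 5))
  # no activity after death
  death_ip <- b$patients$death_date_full[match(b$inpatient$patient_id,
                                               b$patients$patient_id)]
  death_op <- b$patients$death_date_full[match(b$outpatient$patient_id,
                                               b$patients$patient_id)]
  expect_true(all(b$inpatient$admission_date <= death_ip))
  expect_true(all(b$outpatient$date <= death_op))
  # truth covers every patient
  expect_setequal(b$truth$patient_id, b$patients$patient_id)
})

test_that("certain hysterectomy probability gives every patient a surgery spell", {
  p <- stagecost_params(n_patients = 150,
                        stage_probs = single_stage_probs("IA_IB"),
                        survival_5yr = rep(0.999, 6))
  b <- simulate_cohort(p, seed = 2)
  has_hyst <- tapply(grepl("Q07", b$inpatient$opcs_codes),
                     b$inpatient$patient_id, any)
  expect_true(all(b$patients$patient_id %in% names(has_hyst)[has_hyst]))
})

test_that("HRG blanking hits the configured rate", {
  b <- simulate_cohort(stagecost_params(n_patients = 3000), seed = 6)
  n_ep <- nrow(b$inpatient)
  expect_gt(n_ep, 5000)
  frac <- mean(is.na(b$inpatient$hrg_code))
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n_ep))
})

test_that("administrative censoring truncates activity and flags patients", {
  p <- small_params(200)
  b <- simulate_cohort(p, seed = 12)
  bc <- apply_administrative_censoring(b)
  expect_true(all(bc$inpatient$admission_date <= p$censor_cutoff))
  expect_true(all(bc$outpatient$date <= p$censor_cutoff))
  # flag definition: min(death, diagnosis + 5y) beyond cutoff
  pts <- bc$patients
  end <- pmin(ifelse(is.na(pts$death_date), Inf, as.numeric(pts$death_date)),
              as.numeric(pts$diagnosis_date) + floor(5 * 365.25))
  expect_equal(pts$cost_censored, end > as.numeric(p$censor_cutoff))
  # a cutoff after everyone's 5-year mark censors no one
  bc2 <- apply_administrative_censoring(b, cutoff = as.Date("2030-01-01"))
  expect_false(any(bc2$patients$cost_censored))
  # a patient dying before both cutoff and 5y is not censored
  died_early <- !is.na(pts$death_date) & pts$death_date <= p$censor_cutoff &
    yrs(pts$diagnosis_date, pts$death_date) < 5
  expect_false(any(pts$cost_censored[died_early]))
})

test_that("uncensored truth means match the calibration targets", {
  p <- stagecost_params(n_patients = 4000)
  b <- simulate_cohort(p, seed = 31)
  agg <- aggregate(total ~ stage, b$truth, mean)
  nn <- table(b$truth$stage)
  sdv <- aggregate(total ~ stage, b$truth, sd)
  for (s in c("IA_IB", "IC", "II")) {
    se <- sdv$total[sdv$stage == s] / sqrt(nn[[s]])
    expect_lt(abs(agg$total[agg$stage == s] - p$total_cost_5y[s]), 3.5 * se,
              label = paste("stage", s, "truth mean"))
  }
})
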