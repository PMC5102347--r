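# shared fixtures, all built in code

yrs <- function(from, to) as.numeric(to - from) / 365.25

default_cfg <- costing_config()
default_tar <- default_tariffs()

# small parameter sets are cheap to build; cache the full default once
PARAMS_DEFAULT <- stagecost_params()

small_params <- function(n = 300, ...) stagecost_params(n_patients = n, ...)

single_stage_probs <- function(stage) {
  p <- setNames(rep(0, 6), c("AEH", "IA_IB", "IC", "II", "III", "IV"))
  p[stage] <- 1
  p
}

# notification-flow fixture mirroring the published results arithmetic:
# 639 notifications, 48 review exclusions, 97 incomplete-HES, 3 missing stage
exclusion_fixture <- function() {
  n <- 639
  data.frame(
    patient_id = sprintf("N%03d", seq_len(n)),
    notified_icd10 = "C54.1",
    review_excluded = seq_len(n) <= 48,
    hes_incomplete = seq_len(n) > 48 & seq_len(n) <= 145,
    stage = ifelse(seq_len(n) > 145 & seq_len(n) <= 148, NA, "IA_IB"),
    stringsAsFactors = FALSE)
}

# patient-level cost table whose per-stage category means equal the published
# two-year (or five-year total) entries exactly: every patient in a stage
# carries the stage mean
table2_fixture_2y <- function() {
  n <- c(AEH = 15, IA_IB = 192, IC = 62, II = 42, III = 26, IV = 3)
  surgery <- c(4760, 5555, 5175, 5832, 7414, 12843)
  adjuvant <- c(0, 459, 3069, 2953, 5581, 4157)
  further <- c(245, 1507, 1593, 2238, 5620, 0)
  stage <- rep(names(n), n)
  i <- rep(seq_along(n), n)
  data.frame(patient_id = sprintf("T%03d", seq_along(stage)),
             stage = factor(stage, levels = names(n)),
             surgery = surgery[i], adjuvant = adjuvant[i],
             further = further[i], stringsAsFactors = FALSE)
}

table2_fixture_5y <- function() {
  n <- c(AEH = 22, IA_IB = 277, IC = 88, II = 65, III = 34, IV = 5)
  total <- c(7277, 9475, 11707, 13965, 26080, 27570)
  stage <- rep(names(n), n)
  i <- rep(seq_along(n), n)
  data.frame(patient_id = sprintf("F%03d", seq_along(stage)),
             stage = factor(stage, levels = names(n)),
             surgery = total[i], adjuvant = 0, further = 0,
             stringsAsFactors = FALSE)
}

# hand-costed activity fixture: two patients, 21 records, every engine rule
# exercised; expected costs computed by hand in test-costing.R
hand_fixture <- function() {
  pa_dx <- as.Date("2004-01-10")
  pb_dx <- as.Date("2004-03-05")
  patients <- data.frame(
    patient_id = c("PA", "PB"),
    diagnosis_date = c(pa_dx, pb_dx),
    stringsAsFactors = FALSE)
  ip <- data.frame(
    patient_id = c("PA", "PA", "PA", "PA", "PB", "PB"),
    admission_date = as.Date(c("2004-02-01", "2004-02-01", "2004-09-01",
                               "2005-06-01", "2004-04-01", "2004-10-01")),
    discharge_date = as.Date(c("2004-02-07", "2004-02-07", "2004-09-14",
                               "2005-06-02", "2004-04-15", "2004-10-02")),
    hrg_code = c("M05", "M04", "M07", NA, "M05", NA),
    opcs_codes = c("Q07+Q23", "Q18", "T30", "T30", "Q07", "Z99"),
    icd10_codes = "C541",
    specialty = "gynaecology",
    stringsAsFactors = FALSE)
  chemo_dates <- as.Date("2004-06-01") + 21 * (0:5)
  radio_dates <- as.Date("2004-12-01") + 0:4
  op <- data.frame(
    patient_id = c("PA", "PA", "PA", "PA",
                   rep("PB", length(chemo_dates) + length(radio_dates))),
    date = c(as.Date(c("2003-12-01", "2004-05-01", "2006-04-01",
                       "2009-02-01")),
             chemo_dates, radio_dates),
    main_specialty = c("gynaecology", "dermatology", "gynaecology",
                       "gynaecology",
                       rep("medical_oncology", 11)),
    treatment_specialty = c("gynaecology", "dermatology", "gynaecology",
                            "gynaecology",
                            rep("medical_oncology", 11)),
    stringsAsFactors = FALSE)
  list(patients = patients, inpatient = ip, outpatient = op)
}

# minimal survival records with the full covariate set the Cox model expects
make_records <- function(time, status_all, stage, status_ec = 0L, seed = 1) {
  set.seed(seed)
  n <- length(time)
  data.frame(
    patient_id = sprintf("R%05d", seq_len(n)),
    time = time,
    status_all = as.integer(status_all),
    status_ec = as.integer(rep_len(status_ec, n)),
    stage = factor(stage, levels = c("AEH", "IA_IB", "IC", "II", "III", "IV")),
    age65 = rnorm(n),
    bmi = 28 + rnorm(n, 0, 4),
    grade = sample(1:3, n, replace = TRUE),
    histology = factor(sample(c("endometrioid_or_AEH", "other"), n, TRUE,
                              prob = c(0.85, 0.15)),
                       levels = c("endometrioid_or_AEH", "other")),
    imd_quintile = sample(1:5, n, replace = TRUE),
    charlson = sample(0:2, n, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    diagnosis_date = as.Date("2005-06-15"),
    stringsAsFactors = FALSE)
}
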