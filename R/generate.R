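#' Generate the patient table of a synthetic cohort
#'
#' Draws stage, demographics, tumour attributes and deprivation for
#' `params$n_patients` women with endometrial cancer (or AEH), conditioning
#' age, BMI, comorbidity, grade and histology mixes on stage.  Dates of birth
#' are snapped to the 15th of the month; diagnosis dates are day-resolved and
#' uniform over the diagnosis window.  Covariate values are blanked
#' independently at the configured missingness rates.
#'
#' @param params a [stagecost_params()] object.
#' @param seed RNG seed; defaults to `params$seed`.
#' @return data frame with one row per patient.
#' @export
generate_patients <- function(params, seed = params$seed) {
  set.seed(seed)
  n <- params$n_patients
  stage <- factor(sample(STAGES, n, replace = TRUE, prob = params$stage_probs),
                  levels = STAGES)
  si <- as.integer(stage)
  win <- as.numeric(params$diagnosis_window[2] - params$diagnosis_window[1])
  diagnosis_date <- params$diagnosis_window[1] + floor(runif(n, 0, win + 1))
  age <- rnorm(n, params$age_mean[si], params$age_sd[si])
  age <- pmin(pmax(age, 40), 95)
  birth_date <- snap_to_midmonth(diagnosis_date - round(age * DAYS_PER_YEAR))
  bmi <- pmin(pmax(rnorm(n, params$bmi_mean[si], params$bmi_sd[si]), 15), 60)
  charlson <- rbinom(n, 1, params$charlson_pos_prob[si]) *
    (1 + rbinom(n, 1, params$charlson2_given_pos))
  imd_quintile <- sample.int(5, n, replace = TRUE,
                             prob = params$imd_quintile_probs)
  grade_probs <- rbind(AEH = c(0.80, 0.15, 0.05), IA_IB = c(0.55, 0.30, 0.15),
                       IC = c(0.40, 0.35, 0.25), II = c(0.35, 0.35, 0.30),
                       III = c(0.25, 0.35, 0.40), IV = c(0.20, 0.30, 0.50))
  u <- runif(n)
  cp <- t(apply(grade_probs, 1, cumsum))
  grade <- 1L + (u > cp[si, 1]) + (u > cp[si, 2])
  hist_endo_prob <- c(0.99, 0.92, 0.88, 0.85, 0.75, 0.70)
  histology <- factor(ifelse(runif(n) < hist_endo_prob[si],
                             "endometrioid_or_AEH", "other"),
                      levels = c("endometrioid_or_AEH", "other"))
  notified_icd10 <- sample(c("C54.1", "C54.9", "C55"), n, replace = TRUE,
                           prob = c(0.80, 0.15, 0.05))
  mr <- params$missing_rates
  histology[runif(n) < mr$histology] <- NA
  grade[runif(n) < mr$grade] <- NA
  imd_quintile[runif(n) < mr$imd] <- NA
  bmi[runif(n) < mr$bmi] <- NA

  data.frame(patient_id = sprintf("P%05d", seq_len(n)),
             stage = stage,
             birth_date = birth_date,
             diagnosis_date = diagnosis_date,
             age_at_diagnosis = round(elapsed(birth_date, diagnosis_date), 2),
             bmi = round(bmi, 1),
             grade = grade,
             histology = histology,
             imd_quintile = imd_quintile,
             charlson = charlson,
             notified_icd10 = notified_icd10,
             stringsAsFactors = FALSE)
}

#' Attach survival outcomes to a generated patient table
#'
#' Time to death follows a stage-specific exponential law with rate
#' `-log(S5)/5` per year, `S5` being the configured five-year survival
#' (clipped to `[0.005, 0.995]`).  Death dates are snapped to the 15th of the
#' month; deaths after the mortality-linkage cutoff are recorded as alive
#' (the exact time is kept in the hidden `death_date_full` column, which
#' truncates event generation).  A configured fraction of deaths carries
#' endometrial cancer as the underlying cause.
#'
#' @inheritParams generate_patients
#' @param patients output of [generate_patients()].
#' @return `patients` with `death_date`, `death_cause` and internal
#'   `death_date_full` columns added.
#' @export
generate_survival <- function(patients, params, seed = params$seed + 1L) {
  set.seed(seed)
  n <- nrow(patients)
  lambda <- params$calib$lambda[match(patients$stage, params$calib$stage)]
  t_years <- stats::rexp(n, rate = lambda)
  death_exact <- patients$diagnosis_date + round(t_years * DAYS_PER_YEAR)
  death_full <- pmax(snap_to_midmonth(death_exact), patients$diagnosis_date)
  cause <- ifelse(runif(n) < params$ec_death_frac, "EC", "other")
  observed <- death_full <= params$mortality_cutoff
  patients$death_date <- as.Date(ifelse(observed, death_full, NA),
                                 origin = "1970-01-01")
  patients$death_cause <- ifelse(observed, cause, NA_character_)
  patients$death_date_full <- death_full
  patients
}

# draw length of stay for an HRG's LOS model
draw_los <- function(params, hrg, n) {
  los <- params$los[[hrg]]
  los["shift"] + rpois(n, los["mu"])
}

# comorbidity ICD-10 codes (dot-free) consistent with a generated Charlson
# score; C541 (the index cancer) is always present and never scores
comorbidity_codes <- function(charlson) {
  vapply(charlson, function(ch) {
    paste(c("C541", c("I21", "J44")[seq_len(ch)]), collapse = "+")
  }, character(1))
}

#' Generate inpatient episodes and outpatient appointments
#'
#' Each patient receives: 0-3 pre-diagnostic outpatient investigations in the
#' six months before diagnosis; diagnostic work-up inpatient spells shortly
#' after diagnosis; a hysterectomy/BSO spell (stage-specific probability)
#' with Poisson length of stay; an adjuvant oncology-appointment series at
#' 21-day intervals (stage-specific probability and calibrated visit count);
#' and further-treatment events from a two-piece Poisson process whose late
#' rate persists for stages III/IV.  All events are truncated at death.  The
#' configured fraction of inpatient episodes has the HRG code blanked (OPCS
#' codes retained).
#'
#' @inheritParams generate_patients
#' @param patients patient table with survival columns
#'   (see [generate_survival()]).
#' @param tariffs tariff table; must resolve every HRG the generator emits.
#' @return list with `inpatient` and `outpatient` data frames.
#' @export
generate_episodes <- function(patients, tariffs, params,
                              seed = params$seed + 2L) {
  if (nrow(tariffs$tariffs) == 0L) stop("configuration error: empty tariff table")
  set.seed(seed)
  n <- nrow(patients)
  cal <- params$calib
  ci <- match(patients$stage, cal$stage)
  dx <- patients$diagnosis_date
  death <- patients$death_date_full
  comorb <- comorbidity_codes(patients$charlson)

  op <- list()  # outpatient pieces
  ip <- list()  # inpatient pieces

  # (a) pre-diagnostic investigations: 0-3 gynaecology outpatient visits
  n_inv <- rbinom(n, params$prediag_invest_size, params$prediag_invest_prob)
  idx <- rep.int(seq_len(n), n_inv)
  op$prediag <- data.frame(
    patient_id = patients$patient_id[idx],
    date = dx[idx] - floor(runif(length(idx), 1, 180)),
    main_specialty = "gynaecology", treatment_specialty = "gynaecology",
    stringsAsFactors = FALSE)

  # (b) diagnostic work-up inpatient spells on non-overlapping day slots
  n_slots <- length(params$diag_slots)
  n_dg <- pmin(rpois(n, cal$n_diag[ci]), n_slots)
  idx <- rep.int(seq_len(n), n_dg)
  if (length(idx)) {
    slot_days <- unlist(lapply(n_dg[n_dg > 0L], function(k) {
      params$diag_slots[sample.int(n_slots, k)]
    }))
    adm <- dx[idx] + slot_days
    los <- draw_los(params, params$hrg_diag, length(idx))
    ip$diag <- data.frame(
      patient_id = patients$patient_id[idx],
      admission_date = adm, discharge_date = adm + los,
      hrg_code = params$hrg_diag, opcs_codes = params$opcs_diag,
      icd10_codes = comorb[idx], specialty = "gynaecology",
      stringsAsFactors = FALSE)
  }

  # (c) hysterectomy/BSO spell, with an occasional second episode in-spell
  has_h <- rbinom(n, 1, params$hysterectomy_prob[ci]) == 1L
  idx <- which(has_h)
  surgery_date <- rep(as.Date(NA), n)
  if (length(idx)) {
    adm <- dx[idx] + floor(runif(length(idx), params$surgery_days[1],
                                 params$surgery_days[2] + 1))
    surgery_date[idx] <- adm
    los <- draw_los(params, params$hrg_surgery, length(idx))
    main_ep <- data.frame(
      patient_id = patients$patient_id[idx],
      admission_date = adm, discharge_date = adm + los,
      hrg_code = params$hrg_surgery,
      opcs_codes = paste(params$opcs_surgery, collapse = "+"),
      icd10_codes = comorb[idx], specialty = "gynaecology",
      stringsAsFactors = FALSE)
    extra <- runif(length(idx)) < params$extra_episode_prob
    ip$surgery <- rbind(main_ep, within(main_ep[extra, , drop = FALSE], {
      hrg_code <- params$hrg_diag
      opcs_codes <- params$opcs_diag
    }))
  }

  # (d) adjuvant series: oncology appointments every 21 days from day 60
  k_base <- floor(cal$adj_visits[ci])
  k <- (k_base + rbinom(n, 1, cal$adj_visits[ci] - k_base)) *
    rbinom(n, 1, params$adjuvant_prob[ci])
  idx <- rep.int(seq_len(n), k)
  visit_no <- sequence(k)
  if (length(idx)) {
    op$adjuvant <- data.frame(
      patient_id = patients$patient_id[idx],
      date = dx[idx] + params$adjuvant_start_day +
        params$adjuvant_interval_days * (visit_no - 1L),
      main_specialty = "medical_oncology",
      treatment_specialty = "medical_oncology",
      stringsAsFactors = FALSE)
  }

  # (e) further treatment: two-piece Poisson process (early window decaying
  # into a persistent late rate), each event an inpatient readmission or an
  # outpatient review
  win_e <- params$further_early_days
  horizon_days <- floor(5 * DAYS_PER_YEAR)
  width_e <- (win_e[2] - win_e[1]) / DAYS_PER_YEAR
  width_l <- (horizon_days - win_e[2]) / DAYS_PER_YEAR
  n_e <- rpois(n, cal$fur_rate_early[ci] * width_e)
  n_l <- rpois(n, cal$fur_rate_late[ci] * width_l)
  idx <- c(rep.int(seq_len(n), n_e), rep.int(seq_len(n), n_l))
  offs <- c(floor(runif(sum(n_e), win_e[1], win_e[2])),
            floor(runif(sum(n_l), win_e[2], horizon_days)))
  if (length(idx)) {
    o <- order(idx, offs)
    idx <- idx[o]; offs <- offs[o]
    is_ip <- runif(length(idx)) < params$further_inpatient_share[ci[idx]]
    fdates <- dx[idx] + offs
    if (any(is_ip)) {
      adm <- fdates[is_ip]
      los <- draw_los(params, params$hrg_further, sum(is_ip))
      ip$further <- data.frame(
        patient_id = patients$patient_id[idx[is_ip]],
        admission_date = adm, discharge_date = adm + los,
        hrg_code = params$hrg_further, opcs_codes = params$opcs_further,
        icd10_codes = comorb[idx[is_ip]], specialty = "gynaecology",
        stringsAsFactors = FALSE)
    }
    if (any(!is_ip)) {
      op$further <- data.frame(
        patient_id = patients$patient_id[idx[!is_ip]],
        date = fdates[!is_ip],
        main_specialty = "gynaecology", treatment_specialty = "gynaecology",
        stringsAsFactors = FALSE)
    }
  }

  inpatient <- do.call(rbind, ip)
  outpatient <- do.call(rbind, op)

  # truncate at death: no events after the (recorded) death date
  di <- match(inpatient$patient_id, patients$patient_id)
  keep <- inpatient$admission_date <= death[di]
  inpatient <- inpatient[keep, , drop = FALSE]
  di <- di[keep]
  inpatient$discharge_date <- pmin(inpatient$discharge_date, death[di])
  outpatient <- outpatient[
    outpatient$date <= death[match(outpatient$patient_id,
                                   patients$patient_id)], , drop = FALSE]

  # blank the HRG on a fraction of inpatient episodes (OPCS retained)
  blank <- runif(nrow(inpatient)) < params$missing_hrg_rate
  inpatient$hrg_code[blank] <- NA_character_

  o <- order(inpatient$patient_id, inpatient$admission_date,
             inpatient$hrg_code, na.last = TRUE)
  inpatient <- inpatient[o, , drop = FALSE]
  inpatient$episode_start <- inpatient$admission_date
  inpatient$episode_end <- inpatient$discharge_date
  outpatient <- outpatient[order(outpatient$patient_id, outpatient$date), ,
                           drop = FALSE]
  outpatient$hrg_code <- NA_character_
  outpatient$opcs_codes <- ""
  rownames(inpatient) <- rownames(outpatient) <- NULL
  list(inpatient = inpatient, outpatient = outpatient)
}

#' Simulate a complete synthetic bundle
#'
#' Runs [generate_patients()], [generate_survival()] and
#' [generate_episodes()], then costs the *uncensored* event history with
#' [cost_events()] to record per-patient true discounted five-year costs in a
#' held-out truth table (used by recovery tests; never an input to the
#' analysis pipeline).
#'
#' @inheritParams generate_episodes
#' @param config costing configuration used for the truth costing.
#' @return list of class `"stagecost_bundle"` with elements `patients`,
#'   `inpatient`, `outpatient`, `truth` and `params`.
#' @export
simulate_cohort <- function(params = stagecost_params(),
                            seed = params$seed,
                            tariffs = default_tariffs(),
                            config = costing_config()) {
  patients <- generate_patients(params, seed)
  patients <- generate_survival(patients, params, seed + 1L)
  eps <- generate_episodes(patients, tariffs, params, seed + 2L)
  ev <- cost_events(eps$inpatient, eps$outpatient, patients, tariffs, config)
  tot <- patient_costs(ev, patients, horizon_years = config$horizon_years)
  truth <- data.frame(patient_id = patients$patient_id,
                      stage = patients$stage,
                      death_date_full = patients$death_date_full,
                      stringsAsFactors = FALSE)
  truth <- merge(truth, tot, by = "patient_id", all.x = TRUE, sort = TRUE)
  num <- c("surgery", "adjuvant", "further", "total")
  truth[num][is.na(truth[num])] <- 0
  structure(list(params = params, patients = patients,
                 inpatient = eps$inpatient, outpatient = eps$outpatient,
                 truth = truth),
            class = "stagecost_bundle")
}

#' Apply administrative censoring to a bundle
#'
#' Removes all hospital-activity records dated after the cutoff and flags
#' patients whose cost follow-up is incomplete: a patient is cost-censored
#' when `min(death date, diagnosis + 5 years)` falls after the cutoff.
#' Death dates are retained up to the (later) mortality-linkage cutoff, so
#' survival follow-up exceeds cost follow-up.
#'
#' @param bundle a `"stagecost_bundle"`.
#' @param cutoff administrative cutoff date; defaults to the generator's.
#' @return the bundle with truncated activity tables and a `cost_censored`
#'   flag on `patients`.
#' @export
apply_administrative_censoring <- function(bundle,
                                           cutoff = bundle$params$censor_cutoff) {
  stopifnot(inherits(bundle, "stagecost_bundle"))
  pts <- bundle$patients
  horizon_days <- floor(5 * DAYS_PER_YEAR)  # 5-year cost horizon
  end_fu <- pmin(ifelse(is.na(pts$death_date), Inf,
                        as.numeric(pts$death_date)),
                 as.numeric(pts$diagnosis_date) + horizon_days)
  pts$cost_censored <- end_fu > as.numeric(cutoff)
  bundle$patients <- pts
  bundle$inpatient <- bundle$inpatient[
    bundle$inpatient$admission_date <= cutoff, , drop = FALSE]
  bundle$outpatient <- bundle$outpatient[
    bundle$outpatient$date <= cutoff, , drop = FALSE]
  bundle$censor_cutoff <- cutoff
  bundle
}
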