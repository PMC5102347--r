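# FIGO stage categories used throughout (AEH = atypical endometrial
# hyperplasia, handled as the earliest "stage" group)
STAGES <- c("AEH", "IA_IB", "IC", "II", "III", "IV")

check_prob_vector <- function(x, field, sum_to_one = FALSE) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("configuration error in '", field, "': probabilities must lie in [0, 1]")
  }
  if (sum_to_one && abs(sum(x) - 1) > 1e-9) {
    stop("configuration error in '", field, "': probabilities must sum to 1")
  }
  invisible(x)
}

named_stage <- function(x, field) {
  if (length(x) == 1L) x <- rep(x, length(STAGES))
  if (length(x) != length(STAGES)) {
    stop("'", field, "' must have one value per stage (", length(STAGES), ")")
  }
  if (is.null(names(x))) names(x) <- STAGES
  x[STAGES]
}

#' Synthetic-cohort generator parameters
#'
#' Builds the parameter set driving [simulate_cohort()].  Defaults reproduce
#' the stage mix, age/BMI/comorbidity profiles, treatment probabilities,
#' five-year survival and stage-specific mean discounted costs of a published
#' English endometrial-cancer cohort (n = 491; stages AEH through IV), with a
#' 20% missing-HRG rate and small covariate missingness rates.  Event-process
#' intensities (diagnostic work-up spells, adjuvant visit counts, and a
#' two-piece further-treatment rate that decays after month six for early
#' stages but persists for stages III/IV) are solved at construction time so
#' that the population expectation of discounted five-year cost equals
#' `total_cost_5y` per stage under the supplied tariffs and costing
#' configuration.
#'
#' @param n_patients number of patients to generate.
#' @param stage_probs probability of each stage category, summing to 1.
#' @param age_mean,age_sd per-stage age at diagnosis (years).
#' @param bmi_mean,bmi_sd per-stage BMI (kg/m^2).
#' @param charlson_pos_prob per-stage probability of Charlson score >= 1.
#' @param imd_quintile_probs length-5 probability vector over deprivation
#'   quintiles (1 = least deprived).
#' @param hysterectomy_prob,adjuvant_prob per-stage treatment probabilities.
#' @param survival_5yr per-stage five-year survival; clipped to
#'   `[0.005, 0.995]` before the exponential rate is derived.
#' @param surgery_cost_2y,adjuvant_cost_2y,further_cost_2y per-stage mean
#'   discounted cost (GBP 2013) by category at two years.
#' @param total_cost_5y per-stage mean discounted total cost at five years;
#'   the calibration target.
#' @param ec_death_frac fraction of deaths attributed to endometrial cancer.
#' @param missing_rates named list of covariate missingness probabilities
#'   (`histology`, `grade`, `imd`, `bmi`).
#' @param missing_hrg_rate fraction of inpatient episodes with the HRG code
#'   blanked (OPCS codes retained).
#' @param diagnosis_window length-2 `Date`: diagnosis dates drawn uniformly
#'   within it.
#' @param censor_cutoff administrative cutoff of hospital-activity data.
#' @param mortality_cutoff later cutoff of death-registry linkage.
#' @param further_inpatient_share per-stage probability that a
#'   further-treatment event is an inpatient readmission rather than an
#'   outpatient visit.
#' @param seed default RNG seed carried with the parameters.
#' @param tariffs,config tariff table and costing configuration the
#'   calibration assumes; the same objects should be used when costing.
#' @return a list of class `"stagecost_params"`, including a `calib` data
#'   frame with per-stage solved intensities (`lambda`, `n_diag`,
#'   `adj_visits`, `fur_rate_early`, `fur_rate_late`).
#' @seealso [expected_cost_by_stage()] for the implied closed-form means.
#' @export
stagecost_params <- function(n_patients = 491,
                             stage_probs = c(AEH = 22, IA_IB = 277, IC = 88,
                                             II = 65, III = 34, IV = 5) / 491,
                             age_mean = c(63.0, 64.9, 66.6, 66.6, 66.8, 69.4),
                             age_sd = c(6.2, 6.1, 5.8, 5.5, 6.2, 3.0),
                             bmi_mean = c(29.6, 29.4, 28.9, 28.5, 28.3, 27.2),
                             bmi_sd = c(7.0, 6.5, 5.1, 6.2, 5.7, 2.7),
                             charlson_pos_prob = c(0.64, 0.42, 0.31, 0.43,
                                                   0.24, 0.20),
                             imd_quintile_probs = c(0.21, 0.21, 0.21, 0.21,
                                                    0.16),
                             hysterectomy_prob = c(0.91, 1.00, 0.99, 0.98,
                                                   0.94, 0.20),
                             adjuvant_prob = c(0.05, 0.09, 0.45, 0.52,
                                               0.71, 0.80),
                             survival_5yr = c(0.95, 0.94, 0.89, 0.81,
                                              0.56, 0.00),
                             surgery_cost_2y = c(4760, 5555, 5175, 5832,
                                                 7414, 12843),
                             adjuvant_cost_2y = c(0, 459, 3069, 2953,
                                                  5581, 4157),
                             further_cost_2y = c(245, 1507, 1593, 2238,
                                                 5620, 0),
                             total_cost_5y = c(7277, 9475, 11707, 13965,
                                               26080, 27570),
                             ec_death_frac = 39 / 61,
                             missing_rates = list(histology = 0.004,
                                                  grade = 0.032,
                                                  imd = 0.004,
                                                  bmi = 0.008),
                             missing_hrg_rate = 0.20,
                             diagnosis_window = as.Date(c("2002-01-01",
                                                          "2009-12-31")),
                             censor_cutoff = as.Date("2010-03-31"),
                             mortality_cutoff = as.Date("2014-06-15"),
                             further_inpatient_share = c(0.3, 0.3, 0.3, 0.3,
                                                         0.6, 0.6),
                             seed = 1L,
                             tariffs = default_tariffs(),
                             config = costing_config()) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("configuration error in 'n_patients': must be >= 1")
  }
  stage_probs <- named_stage(stage_probs, "stage_probs")
  check_prob_vector(stage_probs, "stage_probs", sum_to_one = TRUE)
  if (length(imd_quintile_probs) != 5L) {
    stop("configuration error in 'imd_quintile_probs': need 5 probabilities")
  }
  check_prob_vector(imd_quintile_probs, "imd_quintile_probs", sum_to_one = TRUE)
  for (f in c("hysterectomy_prob", "adjuvant_prob", "survival_5yr",
              "charlson_pos_prob", "further_inpatient_share")) {
    assign(f, named_stage(get(f), f))
    check_prob_vector(get(f), f)
  }
  for (f in c("age_mean", "age_sd", "bmi_mean", "bmi_sd", "surgery_cost_2y",
              "adjuvant_cost_2y", "further_cost_2y", "total_cost_5y")) {
    assign(f, named_stage(get(f), f))
  }
  mr <- missing_rates
  if (!all(c("histology", "grade", "imd", "bmi") %in% names(mr))) {
    stop("configuration error in 'missing_rates': need histology, grade, imd, bmi")
  }
  check_prob_vector(unlist(mr), "missing_rates")
  check_prob_vector(missing_hrg_rate, "missing_hrg_rate")
  check_prob_vector(ec_death_frac, "ec_death_frac")
  stopifnot(length(diagnosis_window) == 2L,
            diagnosis_window[1] <= diagnosis_window[2])

  p <- structure(list(
    n_patients = as.integer(n_patients),
    stage_probs = stage_probs,
    age_mean = age_mean, age_sd = age_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    charlson_pos_prob = charlson_pos_prob,
    imd_quintile_probs = imd_quintile_probs,
    hysterectomy_prob = hysterectomy_prob,
    adjuvant_prob = adjuvant_prob,
    survival_5yr = survival_5yr,
    surgery_cost_2y = surgery_cost_2y,
    adjuvant_cost_2y = adjuvant_cost_2y,
    further_cost_2y = further_cost_2y,
    total_cost_5y = total_cost_5y,
    ec_death_frac = ec_death_frac,
    missing_rates = mr,
    missing_hrg_rate = missing_hrg_rate,
    diagnosis_window = diagnosis_window,
    censor_cutoff = censor_cutoff,
    mortality_cutoff = mortality_cutoff,
    further_inpatient_share = further_inpatient_share,
    # event-placement constants (days relative to diagnosis); diagnostic
    # work-up spells sit on non-overlapping odd-day slots so that distinct
    # admissions are never merged into one spell
    prediag_invest_size = 3L, prediag_invest_prob = 2 / 3,
    diag_slots = seq(1L, 11L, by = 2L),
    surgery_days = c(14L, 42L),
    adjuvant_start_day = 60L, adjuvant_interval_days = 21L,
    further_early_days = c(60L, 183L),
    extra_episode_prob = 0.15,
    charlson2_given_pos = 0.2,
    # length-of-stay models: LOS = shift + Poisson(mu), per HRG
    los = list(M05 = c(shift = 4, mu = 2.5),
               M04 = c(shift = 1, mu = 0),
               M07 = c(shift = 1, mu = 1.5)),
    hrg_surgery = "M05", hrg_diag = "M04", hrg_further = "M07",
    hrg_chemo = "OPCH", hrg_radio = "OPRT",
    opcs_surgery = c("Q07", "Q23"), opcs_diag = "Q18", opcs_further = "T30",
    seed = as.integer(seed)
  ), class = "stagecost_params")
  p$calib <- calibrate_generator(p, tariffs, config)
  p
}

# expected excess bed days for LOS = shift + Poisson(mu) against a trim point
expected_excess_days <- function(shift, mu, trim) {
  kmax <- max(20, ceiling(mu + 12 * sqrt(mu) + 20))
  k <- 0:kmax
  sum(pmax(0, shift + k - trim) * stats::dpois(k, mu))
}

# expected adjusted (inflated + MFF) cost of one spell of a given HRG
expected_spell_cost <- function(hrg, params, tariffs, config) {
  row <- tariff_row(tariffs, hrg)
  los <- params$los[[hrg]]
  ex <- expected_excess_days(los["shift"], los["mu"], row$trim_point)
  (row$base_tariff + ex * row$excess_rate) * config$inflation_factor * config$mff
}

# survival and discount factors on a daily grid
surv_at <- function(lambda, days) exp(-lambda * days / DAYS_PER_YEAR)
disc_at <- function(rate, days) {
  band <- pmax(0, floor(days / DAYS_PER_YEAR))
  (1 + rate)^(-band)
}

# Solve the per-stage event intensities so that the expected discounted cost
# by category matches the configured targets.  All expectations condition on
# the exponential time-to-death (events are truncated at death) and apply the
# engine's step discounting, so generator and engine agree by construction.
calibrate_generator <- function(params, tariffs, config) {
  F_tar <- config$inflation_factor * config$mff
  op_cost <- params_op_cost(config)
  hyst_cost <- expected_spell_cost(params$hrg_surgery, params, tariffs, config)
  diag_cost <- expected_spell_cost(params$hrg_diag, params, tariffs, config)
  fur_ip_cost <- expected_spell_cost(params$hrg_further, params, tariffs, config)
  chemo_cost <- tariff_row(tariffs, params$hrg_chemo)$base_tariff * F_tar

  horizon_days <- floor(config$horizon_years * DAYS_PER_YEAR)
  two_y_days <- floor(2 * DAYS_PER_YEAR)
  r <- config$discount_rate

  out <- lapply(STAGES, function(s) {
    s5 <- min(max(params$survival_5yr[s], 0.005), 0.995)
    lambda <- -log(s5) / 5

    # diagnosis/surgery: pre-diagnostic investigations + hysterectomy spell
    # + diagnostic work-up spells.  The spell count is Poisson truncated at
    # the number of non-overlapping admission slots; the Poisson mean is
    # solved so the truncated expectation hits the category target.
    e_inv <- params$prediag_invest_size * params$prediag_invest_prob * op_cost
    surg_days <- params$surgery_days[1]:params$surgery_days[2]
    e_hyst <- params$hysterectomy_prob[s] *
      mean(surv_at(lambda, surg_days)) * hyst_cost
    n_slots <- length(params$diag_slots)
    diag_unit <- mean(surv_at(lambda, params$diag_slots)) * diag_cost
    e_min <- function(nu) {   # E[min(Poisson(nu), n_slots)]
      k <- 0:(n_slots - 1)
      sum(k * stats::dpois(k, nu)) + n_slots * stats::ppois(n_slots - 1, nu,
                                                            lower.tail = FALSE)
    }
    deficit <- max(0, params$surgery_cost_2y[s] - e_inv - e_hyst)
    target_count <- deficit / diag_unit
    if (target_count <= 0) {
      n_diag <- 0
    } else if (target_count >= n_slots - 1e-9) {
      n_diag <- 50
    } else {
      n_diag <- stats::uniroot(function(nu) e_min(nu) - target_count,
                               c(1e-9, 50), tol = 1e-10)$root
    }
    e_surg <- e_inv + e_hyst + e_min(n_diag) * diag_unit

    # adjuvant therapy: chemo-pattern series, visit count solved against the
    # two-year category mean
    p_a <- params$adjuvant_prob[s]
    max_visits <- 60L
    t_k <- params$adjuvant_start_day +
      params$adjuvant_interval_days * (0:(max_visits - 1))
    term <- p_a * chemo_cost * surv_at(lambda, t_k) * disc_at(r, t_k)
    term2y <- term * (t_k < two_y_days)
    target_a <- params$adjuvant_cost_2y[s]
    if (target_a <= 0 || p_a <= 0) {
      k_adj <- 0
    } else {
      cum <- cumsum(term2y)
      if (target_a >= cum[max_visits]) {
        k_adj <- max_visits
      } else {
        j <- findInterval(target_a, cum)   # cum[j] <= target < cum[j+1]
        base <- if (j == 0) 0 else cum[j]
        k_adj <- j + (target_a - base) / term2y[j + 1]
      }
    }
    kf <- floor(k_adj)
    e_adj5 <- if (kf > 0) sum(term[seq_len(kf)] * (t_k[seq_len(kf)] < horizon_days)) else 0
    if (k_adj > kf) e_adj5 <- e_adj5 + (k_adj - kf) * term[kf + 1] * (t_k[kf + 1] < horizon_days)

    # further treatment: two-piece Poisson process, rates solved against the
    # two-year further mean and the five-year total.  Inpatient events close
    # enough to a predecessor are merged into its spell by the engine and
    # lose their own tariff; a fixed-point first-order correction inflates
    # the rates by the expected merge loss.
    w_ip <- params$further_inpatient_share[s]
    los_f <- params$los[[params$hrg_further]]
    merge_window <- los_f["shift"] + los_f["mu"] + 1   # mean occupied days
    d_early <- params$further_early_days[1]:(params$further_early_days[2] - 1)
    i_early <- sum(surv_at(lambda, d_early) * disc_at(r, d_early)) / DAYS_PER_YEAR
    d_late <- params$further_early_days[2]:(horizon_days - 1)
    sdl <- surv_at(lambda, d_late) * disc_at(r, d_late)
    i_late5 <- sum(sdl) / DAYS_PER_YEAR
    i_late2 <- sum(sdl[d_late < two_y_days]) / DAYS_PER_YEAR

    f2 <- params$further_cost_2y[s]
    f5 <- max(0, params$total_cost_5y[s] - e_surg - e_adj5)
    r1 <- r2 <- 0
    for (iter in 1:4) {
      delta1 <- 1 - exp(-r1 * w_ip * merge_window / DAYS_PER_YEAR)
      delta2 <- 1 - exp(-r2 * w_ip * merge_window / DAYS_PER_YEAR)
      cb1 <- w_ip * (1 - delta1) * fur_ip_cost + (1 - w_ip) * op_cost
      cb2 <- w_ip * (1 - delta2) * fur_ip_cost + (1 - w_ip) * op_cost
      r2 <- (f5 - f2) / (cb2 * (i_late5 - i_late2))
      r1 <- (f2 - cb2 * r2 * i_late2) / (cb1 * i_early)
      if (r2 < 0) {          # 5y increment below the 2y level: front-load
        r2 <- 0
        r1 <- f5 / (cb1 * i_early)
      } else if (r1 < 0) {   # 2y level below the late-rate share: back-load
        r1 <- 0
        r2 <- f5 / (cb2 * i_late5)
      }
    }
    e_fur5 <- cb1 * r1 * i_early + cb2 * r2 * i_late5
    data.frame(stage = s, lambda = lambda, n_diag = n_diag, adj_visits = k_adj,
               fur_rate_early = r1, fur_rate_late = r2,
               exp_surgery = e_surg, exp_adjuvant_5y = e_adj5,
               exp_further_5y = e_fur5,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

params_op_cost <- function(config) config$default_outpatient_cost * config$mff

#' Expected discounted five-year cost per stage implied by the generator
#'
#' Closed-form population expectations of the calibrated event processes,
#' accounting for death truncation and discounting.  With default parameters
#' the `total_5y` column equals `total_cost_5y` by construction (up to the
#' documented degenerate-target clipping).
#'
#' @param params a [stagecost_params()] object.
#' @return data frame with per-stage expected surgery, adjuvant and further
#'   cost at five years and their total.
#' @export
expected_cost_by_stage <- function(params) {
  cal <- params$calib
  data.frame(stage = cal$stage,
             surgery = cal$exp_surgery,
             adjuvant = cal$exp_adjuvant_5y,
             further = cal$exp_further_5y,
             total_5y = cal$exp_surgery + cal$exp_adjuvant_5y +
               cal$exp_further_5y,
             stringsAsFactors = FALSE)
}

#' @export
print.stagecost_params <- function(x, ...) {
  cat("stagecost generator parameters\n")
  cat("  patients:", x$n_patients, "\n")
  cat("  stages:  ", paste(sprintf("%s=%.3f", names(x$stage_probs),
                                   x$stage_probs), collapse = " "), "\n")
  cat("  diagnosis window:", format(x$diagnosis_window[1]), "to",
      format(x$diagnosis_window[2]), "\n")
  cat("  cost cutoff:", format(x$censor_cutoff),
      " mortality cutoff:", format(x$mortality_cutoff), "\n")
  cat("  calibrated 5y cost targets:",
      paste(sprintf("%s=%.0f", names(x$total_cost_5y), x$total_cost_5y),
            collapse = " "), "\n")
  invisible(x)
}
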