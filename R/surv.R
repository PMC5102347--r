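#' Build one-row-per-patient survival records
#'
#' Time runs from diagnosis to death or to the mortality-linkage cutoff
#' (which extends beyond the cost cutoff).  Deaths whose underlying cause is
#' endometrial cancer are distinguished so that cause-specific models can
#' censor other-cause deaths.
#'
#' @param patients patient table with `diagnosis_date`, `death_date`,
#'   `death_cause` and covariates.
#' @param mortality_cutoff end of death-registry follow-up.
#' @return data frame: `patient_id`, `time` (years, > 0), `status_all`,
#'   `status_ec` (0/1), `stage` and covariates.
#' @export
make_survival_records <- function(patients, mortality_cutoff) {
  died <- !is.na(patients$death_date) &
    patients$death_date <= mortality_cutoff
  end <- as.Date(ifelse(died, patients$death_date, mortality_cutoff),
                 origin = "1970-01-01")
  time <- elapsed(patients$diagnosis_date, end, "years")
  time <- pmax(time, 1 / DAYS_PER_YEAR)  # same-month deaths: half a day floor
  data.frame(patient_id = patients$patient_id,
             time = time,
             status_all = as.integer(died),
             status_ec = as.integer(died & patients$death_cause %in% "EC"),
             stage = patients$stage,
             age65 = patients$age_at_diagnosis - 65,
             bmi = patients$bmi,
             grade = patients$grade,
             histology = patients$histology,
             imd_quintile = patients$imd_quintile,
             charlson = patients$charlson,
             diagnosis_date = patients$diagnosis_date,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier survival by stage
#'
#' Product-limit estimate at a fixed time with Greenwood standard errors
#' (log-transformed CIs, the [survival::survfit()] default).
#'
#' @param records survival records (see [make_survival_records()]).
#' @param t evaluation time in years.
#' @param conf confidence level.
#' @return data frame per stage: `n`, `events`, `surv`, `se`, `conf_low`,
#'   `conf_high`; stages with no patients appear as `NA` rows.
#' @export
km_by_stage <- function(records, t = 5, conf = 0.95) {
  stages <- if (is.factor(records$stage)) levels(records$stage) else
    unique(as.character(records$stage))
  rows <- lapply(stages, function(s) {
    d <- records[records$stage == s, , drop = FALSE]
    if (nrow(d) == 0L) {
      return(data.frame(stage = s, n = 0L, events = NA_integer_,
                        surv = NA_real_, se = NA_real_,
                        conf_low = NA_real_, conf_high = NA_real_))
    }
    fit <- survival::survfit(Surv(time, status_all) ~ 1, data = d,
                             conf.int = conf)
    sm <- summary(fit, times = t, extend = TRUE)
    data.frame(stage = s, n = nrow(d), events = sum(d$status_all),
               surv = sm$surv, se = sm$std.err,
               conf_low = sm$lower, conf_high = sm$upper)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

cox_formula <- function() {
  as.formula(paste(
    "Surv(time, status) ~ age65 + charlson1 + charlson2p + bmi_low +",
    "bmi_high + stage + diag_year + hist_other + grade2 + grade3 +",
    "imd1 + imd2 + imd4 + imd5"))
}

cox_frame <- function(records, covars = NULL, endpoint = "all_cause") {
  d <- records
  if (!is.null(covars)) {
    i <- match(d$patient_id, covars$patient_id)
    for (v in c("bmi", "grade", "histology", "imd_quintile")) {
      d[[v]] <- covars[[v]][i]
    }
  }
  rf <- regression_frame(d)
  rf$time <- d$time
  rf$status <- if (endpoint == "EC") d$status_ec else d$status_all
  rf
}

#' Cause-specific Cox proportional hazards model
#'
#' Partial-likelihood fit (Efron ties) of all-cause or endometrial-cancer
#' mortality on the covariates of the cost regression.  For the
#' cancer-specific endpoint other-cause deaths are censored.  When a
#' multiply-imputed object supplies the covariates, the model is fitted per
#' completed dataset and log-hazard ratios are pooled by Rubin's rules.
#'
#' @param records survival records.
#' @param endpoint `"all_cause"` or `"EC"`.
#' @param covars `NULL` (use the records' own covariates), a completed
#'   covariate data frame, or a `"stagecost_mids"` object.
#' @return list of class `"stagecost_cox"`: `summary` (per-term log-HR, SE,
#'   p), `endpoint`, and `fit` (a [survival::coxph()] fit — on the first
#'   completed dataset when pooled — for diagnostics).
#' @export
fit_cox <- function(records, endpoint = c("all_cause", "EC"), covars = NULL) {
  endpoint <- match.arg(endpoint)
  n_events <- if (endpoint == "EC") sum(records$status_ec) else
    sum(records$status_all)
  if (n_events < 1) stop("no events for endpoint '", endpoint, "'")
  cov_list <- if (inherits(covars, "stagecost_mids")) covars$data else
    list(covars)
  fits <- lapply(cov_list, function(cvd) {
    cfr <- cox_frame(records, cvd, endpoint)
    # keep x/y/model in the fit so diagnostics never re-resolve `cfr`
    survival::coxph(cox_formula(), data = cfr, ties = "efron",
                    x = TRUE, y = TRUE, model = TRUE)
  })
  if (length(fits) > 1L) {
    est <- do.call(rbind, lapply(fits, coef))
    vr <- do.call(rbind, lapply(fits, function(f) diag(vcov(f))))
    pooled <- pool_rubin(est, vr)
    smry <- data.frame(term = rownames(pooled), loghr = pooled$estimate,
                       hr = exp(pooled$estimate), se = pooled$se,
                       p = 2 * pt(-abs(pooled$estimate / pooled$se),
                                  pooled$df),
                       row.names = NULL, stringsAsFactors = FALSE)
  } else {
    f <- fits[[1]]
    s <- summary(f)$coefficients
    smry <- data.frame(term = rownames(s), loghr = s[, "coef"],
                       hr = s[, "exp(coef)"], se = s[, "se(coef)"],
                       p = s[, "Pr(>|z|)"],
                       row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(summary = smry, endpoint = endpoint, fit = fits[[1]]),
            class = "stagecost_cox")
}

#' Proportional-hazards diagnostic (scaled Schoenfeld residuals)
#'
#' Therneau-Grambsch test of the proportional-hazards assumption:
#' correlation of scaled Schoenfeld residuals with Kaplan-Meier-transformed
#' time, per covariate and globally.
#'
#' @param fit a `"stagecost_cox"` object or a [survival::coxph()] fit.
#' @return data frame of per-covariate and `GLOBAL` chi-square statistics
#'   and p-values.
#' @export
ph_test <- function(fit) {
  f <- if (inherits(fit, "stagecost_cox")) fit$fit else fit
  if (f$nevent < 2) stop("proportional-hazards test undefined with < 2 events")
  z <- survival::cox.zph(f, transform = "km")
  tab <- as.data.frame(z$table)
  tab$term <- rownames(z$table)
  rownames(tab) <- NULL
  tab[, c("term", "chisq", "df", "p")]
}
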