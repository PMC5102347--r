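#' Partition follow-up into six-month period costs
#'
#' Splits each patient's five-year costing window into ten six-month periods
#' and records the discounted cost increment per period.  A period is
#' *observed* when it lies wholly before the administrative cutoff, or when
#' the patient's (recorded) death precedes the cutoff — after death no
#' further costs can arise, so the whole history is known.  Periods starting
#' after death are *structural zeros* (death is not censoring).  A period is
#' *censored* when the patient was alive at its start, it lies within five
#' years, and part of it falls beyond the cutoff.  Because death-registry
#' linkage extends past the cost cutoff, periods after a known death date are
#' structural zeros even when cost follow-up stopped earlier.
#'
#' @param traj trajectories from [build_trajectories()].
#' @param patients patient table (diagnosis and death dates, covariates).
#' @param cutoff administrative cost cutoff date; `NULL` means fully
#'   observed.
#' @return object of class `"stagecost_periods"`: list with `cost` (n x 10
#'   matrix, `NA` where censored), `status` (n x 10 character matrix:
#'   `"observed"`, `"censored"`, `"dead"`), `covars` (patient covariates used
#'   by the imputation model) and `cutoff`.
#' @export
partition_followup <- function(traj, patients, cutoff = NULL) {
  stopifnot(inherits(traj, "stagecost_trajectories"))
  n <- nrow(patients)
  stopifnot(identical(traj$patients, patients$patient_id))
  bounds <- seq(0, 60, by = 6)
  cum <- traj$total[, as.character(bounds), drop = FALSE]
  cost <- cum[, -1, drop = FALSE] - cum[, -11, drop = FALSE]
  # period 1 carries the pre-diagnostic window too
  cost[, 1] <- cum[, "6"]
  colnames(cost) <- paste0("y", 1:10)

  death_month <- ifelse(is.na(patients$death_date), Inf,
                        elapsed(patients$diagnosis_date, patients$death_date,
                                "months"))
  obs_month <- if (is.null(cutoff)) rep(Inf, n) else
    elapsed(patients$diagnosis_date, cutoff, "months")
  status <- matrix("observed", n, 10,
                   dimnames = list(patients$patient_id, colnames(cost)))
  for (p in 1:10) {
    p_start <- 6 * (p - 1)
    p_end <- 6 * p
    dead <- p_start >= death_month
    observed <- dead | (death_month <= obs_month) | (p_end <= obs_month)
    status[dead, p] <- "dead"
    status[!observed, p] <- "censored"
  }
  cost[status == "censored"] <- NA_real_
  cost[status == "dead"] <- 0

  covars <- data.frame(
    patient_id = patients$patient_id,
    stage = patients$stage,
    age65 = patients$age_at_diagnosis - 65,
    bmi = patients$bmi,
    grade = patients$grade,
    histology = patients$histology,
    imd_quintile = patients$imd_quintile,
    charlson = patients$charlson,
    diagnosis_date = patients$diagnosis_date,
    death_month = death_month,
    stringsAsFactors = FALSE)
  structure(list(cost = cost, status = status, covars = covars,
                 cutoff = cutoff),
            class = "stagecost_periods")
}

# Bayesian-draw linear model + predictive mean matching.
# Returns imputed values for X_mis rows, each equal to an observed donor y.
pmm_draw <- function(y, X, X_mis, k = 5L) {
  qrx <- qr(X)
  rank <- qrx$rank
  piv <- qrx$pivot[seq_len(rank)]
  Xr <- X[, piv, drop = FALSE]
  qrr <- if (rank < ncol(X)) qr(Xr) else qrx
  beta <- qr.coef(qrr, y)
  res <- y - Xr %*% beta
  df <- max(length(y) - rank, 1)
  s2 <- sum(res^2) / df
  s2_star <- s2 * df / rchisq(1, df)
  R <- qr.R(qrr)
  beta_star <- beta + backsolve(R, rnorm(rank)) * sqrt(s2_star)
  pred_obs <- drop(Xr %*% beta)
  pred_mis <- drop(X_mis[, piv, drop = FALSE] %*% beta_star)

  o <- order(pred_obs)
  po <- pred_obs[o]
  yo <- y[o]
  n_obs <- length(po)
  k <- min(k, n_obs)
  pos <- findInterval(pred_mis, po)
  out <- numeric(length(pred_mis))
  for (i in seq_along(pred_mis)) {
    lo <- max(1L, pos[i] - k)
    hi <- min(n_obs, pos[i] + k)
    cand <- lo:hi
    d <- abs(po[cand] - pred_mis[i])
    sel <- cand[order(d)][seq_len(min(k, length(cand)))]
    out[i] <- yo[sel[sample.int(length(sel), 1L)]]
  }
  out
}

# design matrix for the period-cost models (completed covariates)
period_design <- function(cv, prev = NULL, extra = NULL) {
  X <- model.matrix(~ stage + age65 + bmi + factor(grade) + histology +
                      pmin(charlson, 2) + imd_quintile, data = cv)
  if (!is.null(prev)) X <- cbind(X, prev)
  if (!is.null(extra)) X <- cbind(X, extra)
  X
}

# stochastic multinomial imputation of one categorical covariate given
# stage and age (fitted class probabilities, no parameter draw: missingness
# rates here are a few per mille and the extra variance is negligible)
draw_categorical <- function(values, cv, miss) {
  d_obs <- cv[!miss, , drop = FALSE]
  d_obs$.y <- droplevels(factor(values[!miss]))
  f <- nnet::multinom(.y ~ stage + age65, data = d_obs, trace = FALSE)
  pr <- predict(f, newdata = cv[miss, , drop = FALSE], type = "probs")
  if (is.null(dim(pr))) {
    # vector cases: binary outcome (P of second level) or a single row
    pr <- if (length(f$lev) == 2L) cbind(1 - pr, pr) else
      matrix(pr, nrow = 1)
  }
  lev <- f$lev
  apply(pr, 1, function(p) sample(lev, 1L, prob = p))
}

#' Multiply impute censored period costs and missing covariates
#'
#' Chained-equations imputation: categorical covariates (grade, histology,
#' deprivation quintile) are drawn from multinomial models on stage and age;
#' BMI and the censored six-month period costs are imputed by predictive
#' mean matching (PMM, 5 donors) under a Bayesian linear model.  Period
#' costs are imputed sequentially — administrative censoring is monotone, so
#' each period's model can condition on all earlier (observed or completed)
#' periods plus stage, tumour and patient covariates and survival-linkage
#' information (death within the period and within five years), using donors
#' restricted to patients alive at the period start.  PMM guarantees
#' non-negative imputed costs drawn from the observed support.
#'
#' @param periods a [partition_followup()] object.
#' @param m number of imputations (>= 2).
#' @param seed RNG seed; the result is deterministic given `seed`.
#' @param pmm_k number of PMM donor candidates.
#' @return object of class `"stagecost_mids"`: list with `m`, `data` (list of
#'   `m` completed data frames: covariates, `y1`..`y10`, `total_5y`),
#'   `model` (description string), `seed`, `status`.
#' @export
impute_costs <- function(periods, m = 25L, seed = 1L, pmm_k = 5L) {
  stopifnot(inherits(periods, "stagecost_periods"))
  if (m < 2) stop("m must be >= 2: Rubin pooling is undefined for m < 2")
  set.seed(seed)
  cv0 <- periods$covars
  status <- periods$status
  cost0 <- periods$cost
  n <- nrow(cv0)

  died_5y <- is.finite(cv0$death_month) & cv0$death_month <= 60

  completed <- vector("list", m)
  for (imp in seq_len(m)) {
    cv <- cv0
    # --- covariates (tiny missingness; single chained pass) ---
    for (v in c("grade", "histology", "imd_quintile")) {
      miss <- is.na(cv[[v]])
      if (any(miss)) {
        val <- draw_categorical(cv[[v]], cv, miss)
        cv[[v]][miss] <- if (is.numeric(cv0[[v]])) as.numeric(val) else val
      }
    }
    cv$grade <- as.integer(cv$grade)
    cv$imd_quintile <- as.integer(cv$imd_quintile)
    miss_bmi <- is.na(cv$bmi)
    if (any(miss_bmi)) {
      Xb <- model.matrix(~ stage + age65, data = cv)
      cv$bmi[miss_bmi] <- pmm_draw(cv$bmi[!miss_bmi],
                                   Xb[!miss_bmi, , drop = FALSE],
                                   Xb[miss_bmi, , drop = FALSE], pmm_k)
    }
    # --- period costs, sequential over periods ---
    cost <- cost0
    for (p in 1:10) {
      cen <- status[, p] == "censored"
      if (!any(cen)) next
      alive <- status[, p] != "dead"
      obs <- status[, p] == "observed"
      dies_in_p <- is.finite(cv$death_month) & cv$death_month <= 6 * p &
        cv$death_month > 6 * (p - 1)
      prev <- if (p > 1) cost[, seq_len(p - 1), drop = FALSE] else NULL
      X <- period_design(cv, prev, cbind(dies_in_p, died_5y))
      if (sum(obs) < ncol(X) + 2) {
        stop("imputation model for period ", p,
             " has too few observed donors (", sum(obs), ")")
      }
      cost[cen, p] <- pmm_draw(cost[obs, p], X[obs, , drop = FALSE],
                               X[cen, , drop = FALSE], pmm_k)
    }
    dat <- cbind(cv, as.data.frame(cost))
    dat$total_5y <- rowSums(cost)
    dat$total_2y <- cost[, 1] + cost[, 2] + cost[, 3] + cost[, 4]
    completed[[imp]] <- dat
  }
  structure(list(
    m = m, data = completed,
    model = paste("chained equations: multinomial draws for grade/histology/IMD;",
                  "PMM (Bayesian linear model, 5 donors) for BMI and sequential",
                  "6-month period costs on stage, age, BMI, grade, histology,",
                  "Charlson, IMD, prior periods and survival-linkage indicators"),
    seed = seed, status = status),
    class = "stagecost_mids")
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Point estimate = mean of the per-imputation estimates; total variance
#' `T = W + (1 + 1/m) B` with `W` the mean within-imputation variance and
#' `B` the between-imputation variance.  Degrees of freedom follow
#' Barnard-Rubin when a finite complete-data df is supplied, otherwise the
#' classic large-sample formula.
#'
#' @param estimates numeric matrix (m x p) or vector (length m) of
#'   per-imputation estimates.
#' @param variances matching matrix/vector of squared standard errors.
#' @param dfcom complete-data degrees of freedom (finite for small samples).
#' @param conf confidence level.
#' @return data frame with `estimate`, `W`, `B`, `T`, `se`, `df`,
#'   `conf_low`, `conf_high` per parameter.
#' @export
pool_rubin <- function(estimates, variances, dfcom = Inf, conf = 0.95) {
  if (is.null(dim(estimates))) estimates <- matrix(estimates, ncol = 1)
  if (is.null(dim(variances))) variances <- matrix(variances, ncol = 1)
  if (!all(dim(estimates) == dim(variances))) {
    stop("estimates and variances must have matching dimensions")
  }
  m <- nrow(estimates)
  if (m < 2) stop("m must be >= 2 to pool")
  qbar <- colMeans(estimates)
  w <- colMeans(variances)
  b <- apply(estimates, 2, stats::var)
  t_var <- w + (1 + 1 / m) * b
  # riv = relative increase in variance; guard the B = 0 case
  riv <- ifelse(w > 0, (1 + 1 / m) * b / w, 0)
  df_old <- ifelse(b > 0, (m - 1) * (1 + 1 / riv)^2, Inf)
  dfcom <- rep_len(dfcom, length(qbar))
  lambda <- ifelse(t_var > 0, (1 + 1 / m) * b / t_var, 0)
  df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
  df <- ifelse(is.finite(dfcom), 1 / (1 / df_old + 1 / df_obs), df_old)
  se <- sqrt(t_var)
  qt_ <- ifelse(is.finite(df), qt(1 - (1 - conf) / 2, df),
                stats::qnorm(1 - (1 - conf) / 2))
  out <- data.frame(estimate = qbar, W = w, B = b, T = t_var, se = se,
                    df = df,
                    conf_low = qbar - qt_ * se,
                    conf_high = qbar + qt_ * se)
  if (!is.null(colnames(estimates))) rownames(out) <- colnames(estimates)
  out
}

#' Pooled stage means of five-year cost from a multiply-imputed object
#'
#' @param mids a [impute_costs()] result.
#' @param value column of the completed datasets to summarise
#'   (default `"total_5y"`).
#' @param conf confidence level for the Rubin-t interval.
#' @return data frame per stage (plus an `all` row): `n`, pooled `mean`,
#'   `se`, `conf_low`, `conf_high`, and `median`/`sd` computed on the first
#'   completed dataset (pooling order statistics is ill-defined).
#' @export
pool_stage_means <- function(mids, value = "total_5y", conf = 0.95) {
  stopifnot(inherits(mids, "stagecost_mids"))
  groups <- c(levels(mids$data[[1]]$stage), "all")
  est <- sapply(mids$data, function(d) {
    v <- d[[value]]
    c(tapply(v, d$stage, mean), all = mean(v))
  })
  vars <- sapply(mids$data, function(d) {
    v <- d[[value]]
    c(tapply(v, d$stage, function(x) stats::var(x) / length(x)),
      all = stats::var(v) / length(v))
  })
  n_by <- c(table(mids$data[[1]]$stage), all = nrow(mids$data[[1]]))
  pooled <- pool_rubin(t(est), t(vars), dfcom = n_by - 1, conf = conf)
  d1 <- mids$data[[1]]
  med <- c(tapply(d1[[value]], d1$stage, median), all = median(d1[[value]]))
  sdv <- c(tapply(d1[[value]], d1$stage, sd), all = sd(d1[[value]]))
  data.frame(stage = groups, n = as.integer(n_by),
             mean = pooled$estimate, se = pooled$se,
             conf_low = pooled$conf_low, conf_high = pooled$conf_high,
             median = med, sd = sdv,
             row.names = NULL, stringsAsFactors = FALSE)
}
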