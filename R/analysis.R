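#' Stage-stratified cost summary table
#'
#' Summarises patient-level category costs by stage, with an all-stages row.
#' By construction the per-category means sum to the total mean and the
#' all-stages mean equals the patient-count-weighted mean of the stage rows.
#' For the two-year horizon the input should be the complete-data subset
#' (patients with at least two years of cost follow-up); for five years,
#' use [pool_stage_means()] on a multiply-imputed object instead and this
#' function for any single completed dataset.
#'
#' @param costs data frame with `stage` and numeric `surgery`, `adjuvant`,
#'   `further` columns (one row per patient).
#' @param boot_B bootstrap replicates for a percentile CI of the stage mean
#'   (0 = skip).
#' @param seed seed for the bootstrap.
#' @param conf confidence level.
#' @return data frame per stage plus `all`: `n`, category means, `total_mean`,
#'   `median`, `sd`, and bootstrap CI columns when requested.  Empty stages
#'   appear with `n = 0` and `NA` statistics.
#' @export
summarize_costs <- function(costs, boot_B = 0, seed = 1L, conf = 0.95) {
  stopifnot(all(c("stage", "surgery", "adjuvant", "further") %in% names(costs)))
  costs$total <- costs$surgery + costs$adjuvant + costs$further
  stages <- if (is.factor(costs$stage)) levels(costs$stage) else
    unique(as.character(costs$stage))
  groups <- c(stages, "all")
  rows <- lapply(groups, function(g) {
    d <- if (g == "all") costs else costs[costs$stage == g, , drop = FALSE]
    n <- nrow(d)
    if (n == 0L) {
      return(data.frame(stage = g, n = 0L, surgery = NA_real_,
                        adjuvant = NA_real_, further = NA_real_,
                        total_mean = NA_real_, median = NA_real_,
                        sd = NA_real_))
    }
    data.frame(stage = g, n = n,
               surgery = mean(d$surgery), adjuvant = mean(d$adjuvant),
               further = mean(d$further), total_mean = mean(d$total),
               median = median(d$total),
               sd = if (n > 1) sd(d$total) else 0)
  })
  out <- do.call(rbind, rows)
  if (boot_B > 0) {
    set.seed(seed)
    ci <- t(vapply(groups, function(g) {
      d <- if (g == "all") costs$total else
        costs$total[costs$stage == g]
      if (!length(d)) return(c(NA_real_, NA_real_))
      bootstrap_ci(d, mean, B = boot_B, conf = conf)
    }, numeric(2)))
    out$boot_low <- ci[, 1]
    out$boot_high <- ci[, 2]
  }
  rownames(out) <- NULL
  out
}

#' Non-parametric bootstrap percentile confidence interval
#'
#' Resamples the patient-level sample with replacement `B` times and returns
#' the percentile interval of the statistic.  With a degenerate sample
#' (n = 1) the interval collapses to the point.
#'
#' @param x numeric vector of patient-level values.
#' @param statistic function of a numeric vector.
#' @param B number of replicates (>= 100 recommended).
#' @param conf confidence level.
#' @param seed optional seed (set it for standalone deterministic use; leave
#'   `NULL` inside an outer seeded computation).
#' @return length-2 numeric vector (lower, upper).
#' @export
bootstrap_ci <- function(x, statistic = mean, B = 1000L, conf = 0.95,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  if (n == 1L) {
    s <- statistic(x)
    return(c(s, s))
  }
  reps <- vapply(seq_len(B),
                 function(b) statistic(x[sample.int(n, n, replace = TRUE)]),
                 numeric(1))
  unname(quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
}

#' Bootstrap-with-reimputation confidence intervals for stage means
#'
#' Composes the non-parametric bootstrap with imputation uncertainty:
#' patients are resampled first, then the censored periods of each replicate
#' are completed by a single stochastic imputation, and the percentile
#' interval of the stage means is taken over replicates.
#'
#' @param periods a [partition_followup()] object.
#' @param B bootstrap replicates.
#' @param seed RNG seed.
#' @param conf confidence level.
#' @param pmm_k PMM donor count.
#' @return data frame per stage (plus `all`): `conf_low`, `conf_high`.
#' @export
bootstrap_mi_ci <- function(periods, B = 1000L, seed = 1L, conf = 0.95,
                            pmm_k = 5L) {
  stopifnot(inherits(periods, "stagecost_periods"))
  set.seed(seed)
  n <- nrow(periods$covars)
  stages <- levels(periods$covars$stage)
  reps <- matrix(NA_real_, B, length(stages) + 1,
                 dimnames = list(NULL, c(stages, "all")))
  for (b in seq_len(B)) {
    ix <- sample.int(n, n, replace = TRUE)
    pb <- structure(list(cost = periods$cost[ix, , drop = FALSE],
                         status = periods$status[ix, , drop = FALSE],
                         covars = periods$covars[ix, , drop = FALSE],
                         cutoff = periods$cutoff),
                    class = "stagecost_periods")
    # single stochastic completion inside the replicate
    mi <- impute_costs(pb, m = 2L, seed = sample.int(2^31 - 1, 1), pmm_k = pmm_k)
    d <- mi$data[[1]]
    reps[b, ] <- c(tapply(d$total_5y, d$stage, mean), mean(d$total_5y))
  }
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  ci <- t(apply(reps, 2, quantile, probs = probs, na.rm = TRUE))
  data.frame(stage = rownames(ci), conf_low = ci[, 1], conf_high = ci[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean cost-accumulation curves by stage
#'
#' Group means of the cumulative discounted cost trajectories by month since
#' diagnosis, with the fraction of five-year cost accrued by month six as a
#' companion statistic.
#'
#' @param traj a [build_trajectories()] object (use fully observed or
#'   truth-costed trajectories; censored patients' curves are flat after
#'   their cutoff).
#' @param grouping factor per patient; defaults to stage.
#' @return list with `curves` (month x group matrix of mean cumulative cost)
#'   and `month6_fraction` (named vector per group).
#' @export
accumulation_curves <- function(traj, grouping = traj$stage) {
  stopifnot(inherits(traj, "stagecost_trajectories"))
  g <- factor(grouping)
  curves <- sapply(levels(g), function(lv) {
    colMeans(traj$total[g == lv, , drop = FALSE])
  })
  rownames(curves) <- traj$months
  frac <- curves[as.character(6), ] / curves[as.character(60), ]
  list(curves = curves, month6_fraction = frac)
}

#' Plot cost-accumulation curves
#'
#' @param curves output of [accumulation_curves()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot_accumulation <- function(curves, ...) {
  m <- curves$curves
  graphics::matplot(as.numeric(rownames(m)), m, type = "l", lty = 1,
                    xlab = "months since diagnosis",
                    ylab = "mean cumulative discounted cost (GBP)", ...)
  graphics::legend("topleft", legend = colnames(m), lty = 1,
                   col = seq_len(ncol(m)), bty = "n")
}

# model formula shared by the cost regressions (reference levels: stage AEH,
# grade 1, BMI 18.5-30, middle IMD quintile, Charlson 0)
cost_regression_formula <- function(outcome) {
  as.formula(paste(
    outcome, "~ age65 + charlson1 + charlson2p + bmi_low + bmi_high +",
    "stage + diag_year + hist_other + grade2 + grade3 +",
    "imd1 + imd2 + imd4 + imd5"))
}

regression_frame <- function(d, year_origin = as.Date("2002-01-01")) {
  data.frame(
    age65 = d$age65,
    charlson1 = as.integer(d$charlson == 1),
    charlson2p = as.integer(d$charlson >= 2),
    bmi_low = as.integer(d$bmi < 18.5),
    bmi_high = as.integer(d$bmi > 30),
    stage = droplevels(factor(d$stage)),   # empty stages carry no dummy
    diag_year = floor(elapsed(year_origin, d$diagnosis_date, "years")),
    hist_other = as.integer(d$histology == "other"),
    grade2 = as.integer(d$grade == 2),
    grade3 = as.integer(d$grade == 3),
    imd1 = as.integer(d$imd_quintile == 1),
    imd2 = as.integer(d$imd_quintile == 2),
    imd4 = as.integer(d$imd_quintile == 4),
    imd5 = as.integer(d$imd_quintile == 5))
}

#' Cost regression with pre-specified covariates
#'
#' Ordinary least squares regression of patient-level cost on age (centred
#' on 65), Charlson score (dummies for 1 and 2+), BMI class, stage,
#' diagnosis year (years since January 2002), histological subtype, grade
#' and deprivation quintile (middle quintile as reference).  When given a
#' multiply-imputed object the model is fitted per completed dataset and
#' pooled by Rubin's rules.
#'
#' @param data a completed data frame (columns as produced by
#'   [impute_costs()]'s completed sets plus the outcome) or a
#'   `"stagecost_mids"` object.
#' @param outcome name of the outcome column (e.g. `"total_5y"`,
#'   `"total_2y"`).
#' @return data frame per term: `estimate`, `se`, `statistic`, `p`, plus
#'   pooling columns when multiply imputed.
#' @export
fit_cost_regression <- function(data, outcome = "total_5y") {
  fit_one <- function(d) {
    rf <- regression_frame(d)
    rf$.y <- d[[outcome]]
    X <- model.matrix(cost_regression_formula(".y"), data = cbind(rf))
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
      aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
      stop("collinear design: aliased column(s): ",
           paste(aliased, collapse = ", "))
    }
    f <- lm(cost_regression_formula(".y"), data = rf)
    s <- summary(f)$coefficients
    list(est = s[, 1], var = s[, 2]^2, df = f$df.residual)
  }
  if (inherits(data, "stagecost_mids")) {
    fits <- lapply(data$data, fit_one)
    est <- do.call(rbind, lapply(fits, `[[`, "est"))
    vr <- do.call(rbind, lapply(fits, `[[`, "var"))
    pooled <- pool_rubin(est, vr, dfcom = fits[[1]]$df)
    out <- data.frame(term = rownames(pooled), estimate = pooled$estimate,
                      se = pooled$se,
                      statistic = pooled$estimate / pooled$se,
                      p = 2 * pt(-abs(pooled$estimate / pooled$se),
                                 pooled$df),
                      B = pooled$B, df = pooled$df,
                      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    f1 <- fit_one(data)
    tval <- f1$est / sqrt(f1$var)
    out <- data.frame(term = names(f1$est), estimate = f1$est,
                      se = sqrt(f1$var), statistic = tval,
                      p = 2 * pt(-abs(tval), f1$df),
                      row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}
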