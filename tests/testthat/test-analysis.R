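test_that("summary table satisfies the published arithmetic identities", {
  tab <- summarize_costs(table2_fixture_2y())
  iii <- tab[tab$stage == "III", ]
  expect_equal(iii$surgery + iii$adjuvant + iii$further, 18615)
  expect_equal(iii$total_mean, 18615)
  all_row <- tab[tab$stage == "all", ]
  expect_equal(round(all_row$total_mean), 9197)
  # the all-stages row is the n-weighted mean of the stage rows
  st <- tab[tab$stage != "all", ]
  expect_equal(all_row$total_mean,
               sum(st$n * st$total_mean) / sum(st$n))

  tab5 <- summarize_costs(table2_fixture_5y())
  all5 <- tab5[tab5$stage == "all", ]
  st5 <- tab5[tab5$stage != "all", ]
  expect_equal(all5$total_mean, sum(st5$n * st5$total_mean) / sum(st5$n))
  expect_lt(abs(all5$total_mean - 11705), 2)  # printed-precision rounding
})

test_that("summary handles degenerate inputs", {
  one <- data.frame(stage = factor("II", levels = c("AEH", "II")),
                    surgery = 4000, adjuvant = 0, further = 500)
  tab <- summarize_costs(one)
  row <- tab[tab$stage == "II", ]
  expect_equal(row$total_mean, 4500)
  expect_equal(row$median, 4500)
  expect_equal(row$sd, 0)
  empty <- tab[tab$stage == "AEH", ]
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$total_mean))
})

test_that("bootstrap CI behaves at the edges and is deterministic", {
  expect_equal(bootstrap_ci(rep(5, 40), mean, B = 200, seed = 1), c(5, 5))
  expect_equal(bootstrap_ci(7), c(7, 7))          # n = 1 collapses
  set.seed(2)
  x <- rexp(300, 1 / 10000)
  ci_a <- bootstrap_ci(x, mean, B = 500, seed = 9)
  ci_b <- bootstrap_ci(x, mean, B = 500, seed = 9)
  expect_identical(ci_a, ci_b)
  expect_lte(ci_a[1], mean(x))
  expect_gte(ci_a[2], mean(x))
})

test_that("bootstrap percentile CI attains near-nominal coverage", {
  set.seed(30)
  true_mean <- 10000
  hits <- vapply(1:100, function(r) {
    x <- rexp(300, 1 / true_mean)
    ci <- bootstrap_ci(x, mean, B = 200)
    ci[1] <= true_mean && true_mean <= ci[2]
  }, logical(1))
  expect_gt(mean(hits), 0.88)
})

test_that("accumulation curves are consistent with patient costs", {
  p <- small_params(200)
  b <- simulate_cohort(p, seed = 24)
  ev <- cost_events(b$inpatient, b$outpatient, b$patients, default_tar,
                    default_cfg)
  tr <- build_trajectories(ev, b$patients, default_cfg)
  cur <- accumulation_curves(tr)
  # curve endpoint equals the five-year mean per stage
  pc <- patient_costs(ev, b$patients)
  pc <- merge(data.frame(patient_id = b$patients$patient_id,
                         stage = b$patients$stage), pc, all.x = TRUE)
  pc[is.na(pc)] <- 0
  means <- tapply(pc$total, pc$stage, mean)
  for (s in names(means)) {
    if (is.na(means[s])) next
    expect_equal(unname(cur$curves["60", s]), unname(means[s]),
                 tolerance = 1e-9)
  }
  # a single-patient group reproduces that patient's trajectory
  solo <- build_trajectories(ev[ev$patient_id == b$patients$patient_id[1], ],
                             b$patients[1, , drop = FALSE], default_cfg)
  cs <- accumulation_curves(solo, grouping = rep("g", 1))
  expect_equal(unname(cs$curves[, "g"]), unname(solo$total[1, ]))
})

test_that("cost regression recovers known linear effects and flags aliasing", {
  set.seed(41)
  n <- 1500
  d <- data.frame(
    patient_id = sprintf("S%04d", 1:n),
    stage = factor(sample(c("AEH", "IA_IB", "III"), n, TRUE,
                          prob = c(0.2, 0.5, 0.3)),
                   levels = c("AEH", "IA_IB", "IC", "II", "III", "IV")),
    age65 = rnorm(n), bmi = 27 + rnorm(n, 0, 4),
    grade = sample(1:3, n, TRUE),
    histology = factor(sample(c("endometrioid_or_AEH", "other"), n, TRUE),
                       levels = c("endometrioid_or_AEH", "other")),
    imd_quintile = sample(1:5, n, TRUE),
    charlson = sample(0:2, n, TRUE),
    diagnosis_date = as.Date("2004-06-15") + sample(0:1000, n, TRUE))
  beta_ia <- 1600; beta_iii <- 9700; beta_g3 <- 3800
  d$total_5y <- 5000 + beta_ia * (d$stage == "IA_IB") +
    beta_iii * (d$stage == "III") + beta_g3 * (d$grade == 3) +
    rnorm(n, 0, 3000)
  fit <- fit_cost_regression(d, "total_5y")
  for (chk in list(c("stageIA_IB", beta_ia), c("stageIII", beta_iii),
                   c("grade3", beta_g3))) {
    row <- fit[fit$term == chk[1], ]
    expect_lt(abs(row$estimate - as.numeric(chk[2])), 3 * row$se,
              label = chk[1])
  }
  # ordering property: later stage costs more
  expect_gt(fit$estimate[fit$term == "stageIII"],
            fit$estimate[fit$term == "stageIA_IB"])
  # zero-variance covariate is rejected with an aliasing error
  d_bad <- d
  d_bad$charlson <- 1
  expect_error(fit_cost_regression(d_bad, "total_5y"), "aliased")
})

test_that("pooled regression across imputations keeps the coefficient scale", {
  b <- simulate_cohort(small_params(500), seed = 26)
  bc <- apply_administrative_censoring(b)
  ev <- cost_events(bc$inpatient, bc$outpatient, bc$patients, default_tar,
                    default_cfg)
  tr <- build_trajectories(ev, bc$patients, default_cfg,
                           cutoff = PARAMS_DEFAULT$censor_cutoff)
  per <- partition_followup(tr, bc$patients, PARAMS_DEFAULT$censor_cutoff)
  mi <- impute_costs(per, m = 4, seed = 61)
  fit <- fit_cost_regression(mi, "total_5y")
  expect_true(all(c("stageIII", "grade3", "diag_year") %in% fit$term))
  expect_gt(fit$estimate[fit$term == "stageIII"],
            fit$estimate[fit$term == "stageIA_IB"])
  expect_true(all(is.finite(fit$se)))
})
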