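test_that("HRG resolution prefers the recorded code and falls back to OPCS", {
  expect_equal(resolve_hrg("M05", "Q18", default_tar), "M05")
  expect_equal(resolve_hrg(NA, "Q07", default_tar), "M05")
  expect_equal(resolve_hrg(NA, "Z99+T30", default_tar), "M07")
  expect_true(is.na(resolve_hrg(NA, "Z99", default_tar)))
  # exhaustive check of the packaged map
  for (op in names(default_tar$opcs_map)) {
    expect_equal(resolve_hrg(NA, op, default_tar),
                 unname(default_tar$opcs_map[op]))
  }
})

test_that("spell construction merges shared and contiguous intervals", {
  ep <- data.frame(
    patient_id = c("A", "A", "A", "B"),
    admission_date = as.Date(c("2004-01-01", "2004-01-01", "2004-03-01",
                               "2004-01-05")),
    discharge_date = as.Date(c("2004-01-08", "2004-01-08", "2004-03-03",
                               "2004-01-06")),
    hrg_code = "M05", opcs_codes = "Q07", stringsAsFactors = FALSE)
  sp <- build_spells(ep)
  expect_equal(sp$spell[sp$patient_id == "A"], c(1L, 1L, 2L))
  expect_equal(sp$spell[sp$patient_id == "B"], 1L)
  ep_bad <- ep
  ep_bad$discharge_date[1] <- as.Date("2003-12-25")
  expect_error(build_spells(ep_bad), "negative length of stay")
})

test_that("spell costing uses the dominant episode and excess bed days", {
  cfg <- default_cfg
  uplift <- cfg$inflation_factor * cfg$mff
  # single episode within trim: tariff only
  one <- data.frame(patient_id = "A",
                    admission_date = as.Date("2004-01-01"),
                    discharge_date = as.Date("2004-01-05"),
                    hrg_code = "M05", opcs_codes = "Q07",
                    stringsAsFactors = FALSE)
  c1 <- cost_spells(one, default_tar, cfg)
  expect_equal(c1$nominal_cost, 3700)
  expect_equal(c1$adjusted_cost, 3700 * uplift)
  expect_equal(c1$excess_days, 0)
  # two episodes, most expensive wins
  two <- rbind(one, transform(one, hrg_code = "M04", opcs_codes = "Q18"))
  c2 <- cost_spells(two, default_tar, cfg)
  expect_equal(nrow(c2), 1)
  expect_equal(c2$nominal_cost, 3700)
  # beyond the trim point the daily rate applies: 11 days vs trim 8
  long <- transform(one, discharge_date = as.Date("2004-01-12"))
  c3 <- cost_spells(long, default_tar, cfg)
  expect_equal(c3$excess_days, 3)
  expect_equal(c3$nominal_cost, 3700 + 3 * 225)
  # cost is non-decreasing in length of stay
  los_grid <- 1:15
  costs <- vapply(los_grid, function(L) {
    sp <- transform(one, discharge_date = one$admission_date + L)
    cost_spells(sp, default_tar, cfg)$nominal_cost
  }, numeric(1))
  expect_true(all(diff(costs) >= 0))
})

test_that("outpatient inclusion and series detection follow the rules", {
  cfg <- default_cfg
  fx <- hand_fixture()
  op <- cost_outpatient(fx$outpatient, default_tar, cfg)
  # dermatology appointment without codes is excluded
  expect_equal(nrow(op), nrow(fx$outpatient) - 1)
  # chemo series: 6 oncology visits 21 days apart
  pb <- op[op$patient_id == "PB", ]
  expect_equal(sum(pb$series %in% "chemo"), 6)
  expect_equal(unique(pb$nominal_cost[pb$series %in% "chemo"]), 380)
  # radiotherapy: 5 near-daily fractions
  expect_equal(sum(pb$series %in% "radio"), 5)
  # plain gynae follow-up gets the flat cost with MFF only
  pa <- op[op$patient_id == "PA", ]
  expect_equal(unique(pa$adjusted_cost), 135 * 1.08)
})

test_that("discounting is anchored on diagnosis-year bands", {
  cfg <- default_cfg
  dx <- as.Date("2004-01-10")
  expect_equal(discount(1000, dx + 90, dx, cfg), 1000)       # first year
  expect_equal(discount(1000, dx - 60, dx, cfg), 1000)       # pre-diagnostic
  expect_equal(discount(1000, dx + round(2.5 * 365.25), dx, cfg),
               1000 / 1.035^2, tolerance = 1e-10)            # = 933.51
  cfg0 <- costing_config(discount_rate = 0)
  expect_equal(discount(1000, dx + 1400, dx, cfg0), 1000)
})

test_that("engine output equals the hand-computed fixture line by line", {
  fx <- hand_fixture()
  ev <- cost_events(fx$inpatient, fx$outpatient, fx$patients, default_tar,
                    default_cfg)
  expect_equal(attr(ev, "n_unresolved"), 1L)
  expect_equal(attr(ev, "n_beyond_horizon"), 1L)

  pa <- ev[ev$patient_id == "PA", ]
  pb <- ev[ev$patient_id == "PB", ]
  # PA: prediag visit, merged hysterectomy spell, readmission with excess
  # days, OPCS-resolved episode, discounted follow-up visit
  expect_equal(nrow(pa), 5)
  expect_equal(pa$discounted_cost[pa$event_date == as.Date("2003-12-01")],
               145.80)
  hyst <- pa[pa$event_date == as.Date("2004-02-01"), ]
  expect_equal(hyst$nominal_cost, 3700)         # dominant episode, merged
  expect_equal(hyst$discounted_cost, 4795.20)
  readm <- pa[pa$event_date == as.Date("2004-09-01"), ]
  expect_equal(readm$excess_days, 8)            # LOS 13 vs trim 5
  expect_equal(readm$nominal_cost, 3000)        # 1400 + 8 x 200
  expect_equal(readm$discounted_cost, 3888)
  opcs_ep <- pa[pa$event_date == as.Date("2005-06-01"), ]
  expect_equal(opcs_ep$hrg_resolved, "M07")
  expect_equal(opcs_ep$discounted_cost, 1814.4 / 1.035, tolerance = 1e-10)
  fup <- pa[pa$event_date == as.Date("2006-04-01"), ]
  expect_equal(fup$discounted_cost, 145.8 / 1.035^2, tolerance = 1e-10)
  expect_equal(as.character(pa$category),
               c("surgery", "surgery", "further", "further", "further"))

  # PB: hysterectomy with 6 excess days, zero-cost unresolved spell,
  # 6 chemo + 5 radio adjuvant visits
  expect_equal(nrow(pb), 13)
  hb <- pb[pb$event_date == as.Date("2004-04-01"), ]
  expect_equal(hb$nominal_cost, 5050)           # 3700 + 6 x 225
  expect_equal(hb$discounted_cost, 6544.80)
  unres <- pb[pb$event_date == as.Date("2004-10-01"), ]
  expect_equal(unres$discounted_cost, 0)
  expect_equal(sum(pb$category == "adjuvant"), 11)
  expect_equal(sum(pb$discounted_cost[pb$category == "adjuvant"]),
               6 * 492.48 + 5 * 155.52)

  # per-patient totals against the hand spreadsheet
  pc <- patient_costs(ev, fx$patients)
  expect_equal(pc$surgery[pc$patient_id == "PA"], 4795.20 + 145.80)
  expect_equal(pc$further[pc$patient_id == "PA"],
               3888 + 1814.4 / 1.035 + 145.8 / 1.035^2)
  expect_equal(pc$adjuvant[pc$patient_id == "PB"], 3732.48)
  expect_equal(pc$total, pc$surgery + pc$adjuvant + pc$further)
})

test_that("doubling every tariff doubles tariff-derived costs exactly", {
  fx <- hand_fixture()
  tar2 <- default_tar
  tar2$tariffs$base_tariff <- tar2$tariffs$base_tariff * 2
  tar2$tariffs$excess_rate <- tar2$tariffs$excess_rate * 2
  cfg2 <- costing_config(default_outpatient_cost = 135 * 2)
  ev1 <- cost_events(fx$inpatient, fx$outpatient, fx$patients, default_tar,
                     default_cfg)
  ev2 <- cost_events(fx$inpatient, fx$outpatient, fx$patients, tar2, cfg2)
  expect_equal(ev2$discounted_cost, 2 * ev1$discounted_cost)
})

test_that("trajectories step at event months and conserve categories", {
  pts <- data.frame(patient_id = "X",
                    diagnosis_date = as.Date("2004-01-10"),
                    stage = factor("IA_IB", levels = c("AEH", "IA_IB", "IC",
                                                       "II", "III", "IV")),
                    stringsAsFactors = FALSE)
  ev <- data.frame(patient_id = "X",
                   event_date = as.Date("2004-02-20"),
                   category = factor("surgery",
                                     levels = c("surgery", "adjuvant",
                                                "further")),
                   discounted_cost = 5000,
                   stringsAsFactors = FALSE)
  tr <- build_trajectories(ev, pts, default_cfg)
  expect_equal(unname(tr$total[1, "0"]), 0)
  expect_equal(unname(tr$total[1, "2"]), 5000)
  expect_equal(unname(tr$total[1, "60"]), 5000)
  expect_true(all(diff(tr$total[1, ]) >= 0))

  # conservation on simulated data: category curves sum to the total
  p <- small_params(150)
  b <- simulate_cohort(p, seed = 21)
  evs <- cost_events(b$inpatient, b$outpatient, b$patients, default_tar,
                     default_cfg)
  trs <- build_trajectories(evs, b$patients, default_cfg)
  recon <- trs$category$surgery + trs$category$adjuvant +
    trs$category$further
  expect_equal(recon, trs$total)
  # discounted never exceeds adjusted, with equality only in band 0
  expect_true(all(evs$discounted_cost <= evs$adjusted_cost + 1e-9))
})

test_that("late-stage cohorts accrue more of their cost after month six", {
  p3 <- stagecost_params(n_patients = 400,
                         stage_probs = single_stage_probs("III"))
  p1 <- stagecost_params(n_patients = 400,
                         stage_probs = single_stage_probs("IA_IB"))
  b3 <- simulate_cohort(p3, seed = 22)
  b1 <- simulate_cohort(p1, seed = 23)
  frac_late <- function(b) {
    ev <- cost_events(b$inpatient, b$outpatient, b$patients, default_tar,
                      default_cfg)
    tr <- build_trajectories(ev, b$patients, default_cfg)
    cur <- accumulation_curves(tr)
    unname(cur$month6_fraction)
  }
  expect_gt(frac_late(b1), frac_late(b3))  # early stage front-loads cost
})
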