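write_tbl <- function(d, path) {
  for (cl in names(d)) if (inherits(d[[cl]], "Date")) {
    d[[cl]] <- format(d[[cl]], "%Y-%m-%d")
  }
  write.csv(d, path, row.names = FALSE, na = "")
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> assemble -> cost -> censor -> impute ->
#' analyse-costs -> analyse-survival, writing every intermediate and final
#' table as CSV into `out_dir` together with a reproducibility manifest
#' (seed, parameters digest, file checksums).  Identical seed and
#' parameters give byte-identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param params generator parameters ([stagecost_params()]).
#' @param seed master seed for all stochastic stages.
#' @param tariffs,config tariff table and costing configuration.
#' @param m number of imputations.
#' @param boot_B bootstrap replicates for the two-year complete-data CI
#'   (0 skips).
#' @param horizons character subset of `c("2y", "5y")`.
#' @return invisibly, a list with the principal in-memory results.
#' @export
run_pipeline <- function(out_dir, params = stagecost_params(), seed = params$seed,
                         tariffs = default_tariffs(), config = costing_config(),
                         m = 25L, boot_B = 0L, horizons = c("2y", "5y")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- simulate -------------------------------------------------------
  bundle <- step("simulate", simulate_cohort(params, seed, tariffs, config))
  write_tbl(bundle$patients[setdiff(names(bundle$patients),
                                    "death_date_full")],
            file.path(out_dir, "patients.csv"))
  write_tbl(bundle$inpatient, file.path(out_dir, "inpatient.csv"))
  write_tbl(bundle$outpatient, file.path(out_dir, "outpatient.csv"))
  write_tbl(bundle$truth, file.path(out_dir, "truth.csv"))

  # --- assemble -------------------------------------------------------
  cb <- step("assemble", {
    b <- apply_administrative_censoring(bundle, params$censor_cutoff)
    asm <- assemble_cohort(b$patients, b$inpatient)
    list(bundle = b, asm = asm)
  })
  censored <- cb$bundle
  cohort <- cb$asm$cohort
  write_tbl(cohort[setdiff(names(cohort), "death_date_full")],
            file.path(out_dir, "cohort.csv"))
  jsonlite::write_json(cb$asm$report, file.path(out_dir, "exclusions.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  # --- cost -----------------------------------------------------------
  costed <- step("cost", {
    ev <- cost_events(censored$inpatient, censored$outpatient, cohort,
                      tariffs, config)
    traj <- build_trajectories(ev, cohort, config, cutoff = params$censor_cutoff)
    list(events = ev, traj = traj)
  })
  write_tbl(costed$events, file.path(out_dir, "costed_events.csv"))

  # --- impute ---------------------------------------------------------
  periods <- step("partition",
                  partition_followup(costed$traj, cohort,
                                     cutoff = params$censor_cutoff))
  mids <- step("impute", impute_costs(periods, m = m, seed = seed + 10L))

  # --- analyse costs --------------------------------------------------
  res <- list(bundle = bundle, cohort = cohort, report = cb$asm$report,
              events = costed$events, trajectories = costed$traj,
              periods = periods, mids = mids)
  if ("2y" %in% horizons) {
    two_y <- step("analyze-costs-2y", {
      sub <- cohort[elapsed(cohort$diagnosis_date, params$censor_cutoff,
                            "years") >= 2, , drop = FALSE]
      pc <- patient_costs(costed$events, sub, horizon_years = 2)
      pc <- merge(sub["patient_id"], pc, by = "patient_id", all.x = TRUE)
      pc[is.na(pc)] <- 0
      pc$stage <- sub$stage[match(pc$patient_id, sub$patient_id)]
      summarize_costs(pc, boot_B = boot_B, seed = seed + 20L)
    })
    write_tbl(two_y, file.path(out_dir, "summary_2y.csv"))
    res$summary_2y <- two_y
  }
  if ("5y" %in% horizons) {
    five_y <- step("analyze-costs-5y", pool_stage_means(mids))
    write_tbl(five_y, file.path(out_dir, "summary_5y.csv"))
    reg <- step("regression", fit_cost_regression(mids, "total_5y"))
    write_tbl(reg, file.path(out_dir, "regression_5y.csv"))
    curves <- step("curves", accumulation_curves(costed$traj))
    write_tbl(data.frame(month = as.numeric(rownames(curves$curves)),
                         curves$curves, check.names = FALSE),
              file.path(out_dir, "curves.csv"))
    res$summary_5y <- five_y
    res$regression_5y <- reg
    res$curves <- curves
  }

  # --- analyse survival -----------------------------------------------
  surv_res <- step("analyze-survival", {
    rec <- make_survival_records(cohort, params$mortality_cutoff)
    km <- km_by_stage(rec, t = 5)
    cox_all <- fit_cox(rec, "all_cause", covars = mids)
    cox_ec <- if (sum(rec$status_ec) > 0) fit_cox(rec, "EC", covars = mids)
      else NULL
    list(records = rec, km = km, cox_all = cox_all, cox_ec = cox_ec,
         ph = ph_test(cox_all))
  })
  write_tbl(surv_res$km, file.path(out_dir, "km.csv"))
  write_tbl(surv_res$cox_all$summary, file.path(out_dir, "cox_all_cause.csv"))
  if (!is.null(surv_res$cox_ec)) {
    write_tbl(surv_res$cox_ec$summary, file.path(out_dir, "cox_ec.csv"))
  }
  write_tbl(surv_res$ph, file.path(out_dir, "ph_test.csv"))
  res$survival <- surv_res

  # --- manifest -------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    seed = seed, m = m, n_patients = params$n_patients,
    censor_cutoff = format(params$censor_cutoff),
    mortality_cutoff = format(params$mortality_cutoff),
    config = config[c("mff", "inflation_factor", "default_outpatient_cost",
                      "discount_rate", "horizon_years")],
    file_md5 = as.list(tools::md5sum(file.path(out_dir, files))),
    elapsed_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
  names(manifest$file_md5) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
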