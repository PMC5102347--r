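#' Resolve the HRG code of an episode
#'
#' Returns the recorded HRG where present and known to the tariff table;
#' otherwise falls back to the first OPCS procedure code with an entry in the
#' OPCS-to-HRG map.  Episodes resolving to neither are returned as `NA`
#' (the engine costs them at zero and counts them in a diagnostic).
#'
#' @param hrg_code character vector of recorded HRG codes (`NA` = missing).
#' @param opcs_codes character vector of `"+"`-separated OPCS codes.
#' @param tariffs a [load_tariffs()] object.
#' @return character vector of resolved HRG codes (`NA` = unresolvable).
#' @export
resolve_hrg <- function(hrg_code, opcs_codes, tariffs) {
  out <- ifelse(!is.na(hrg_code) & hrg_code %in% tariffs$tariffs$hrg,
                hrg_code, NA_character_)
  todo <- which(is.na(out))
  if (length(todo)) {
    mapped <- vapply(strsplit(ifelse(is.na(opcs_codes[todo]), "",
                                     opcs_codes[todo]), "+", fixed = TRUE),
                     function(codes) {
                       hit <- tariffs$opcs_map[codes]
                       hit <- hit[!is.na(hit)]
                       if (length(hit)) hit[[1]] else NA_character_
                     }, character(1))
    out[todo] <- mapped
  }
  out
}

#' Group inpatient episodes into spells
#'
#' A spell runs from hospital admission to discharge and may comprise several
#' consultant episodes.  Episodes of one patient whose admission intervals
#' are identical, overlapping or contiguous are merged into one spell.
#'
#' @param episodes inpatient episode data frame with `patient_id`,
#'   `admission_date`, `discharge_date`.
#' @return `episodes` with a `spell` integer column (unique within patient),
#'   ordered by patient and admission date.
#' @export
build_spells <- function(episodes) {
  if (any(as.numeric(episodes$discharge_date - episodes$admission_date) < 0)) {
    bad <- which(episodes$discharge_date < episodes$admission_date)
    stop("validation error: negative length of stay in episode row(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  o <- order(episodes$patient_id, episodes$admission_date,
             episodes$discharge_date)
  episodes <- episodes[o, , drop = FALSE]
  n <- nrow(episodes)
  if (n == 0L) { episodes$spell <- integer(0); return(episodes) }
  new_pat <- c(TRUE, episodes$patient_id[-1] != episodes$patient_id[-n])
  spell <- integer(n)
  cur_end <- as.numeric(episodes$discharge_date[1])
  spell[1] <- 1L
  adm <- as.numeric(episodes$admission_date)
  dis <- as.numeric(episodes$discharge_date)
  for (i in seq_len(n)[-1]) {
    if (new_pat[i] || adm[i] > cur_end) {
      spell[i] <- if (new_pat[i]) 1L else spell[i - 1] + 1L
      cur_end <- dis[i]
    } else {
      spell[i] <- spell[i - 1]
      cur_end <- max(cur_end, dis[i])
    }
  }
  episodes$spell <- spell
  rownames(episodes) <- NULL
  episodes
}

#' Cost inpatient spells under casemix tariff rules
#'
#' Per spell: every component episode is resolved to an HRG; the nominal cost
#' is the base tariff of the most expensive episode (the dominant episode;
#' ties go to the earliest).  If the spell length of stay exceeds the
#' dominant HRG's trim point, each excess bed day is reimbursed at that HRG's
#' daily rate.  The adjusted cost applies the inflation uplift and the market
#' forces factor.  Episodes resolving to no HRG contribute a zero tariff; a
#' spell with no resolvable episode is costed at zero and counted in the
#' `n_unresolved` attribute.
#'
#' @param episodes inpatient episodes (see [build_spells()]; the `spell`
#'   column is added if absent).
#' @param tariffs a [load_tariffs()] object.
#' @param config a [costing_config()].
#' @return one row per spell: `patient_id`, `event_date` (admission),
#'   `discharge_date`, `hrg_resolved`, `los`, `excess_days`, `nominal_cost`,
#'   `adjusted_cost`, `opcs_codes` (all codes in the spell), `source`.
#' @export
cost_spells <- function(episodes, tariffs, config) {
  if (is.null(episodes$spell)) episodes <- build_spells(episodes)
  if (nrow(episodes) == 0L) {
    return(structure(data.frame(), n_unresolved = 0L))
  }
  hrg <- resolve_hrg(episodes$hrg_code, episodes$opcs_codes, tariffs)
  ti <- match(hrg, tariffs$tariffs$hrg)
  base <- ifelse(is.na(ti), 0, tariffs$tariffs$base_tariff[ti])

  key <- paste(episodes$patient_id, episodes$spell, sep = "\r")
  key <- factor(key, levels = unique(key))   # keeps admission order
  grp <- as.integer(key)
  # dominant episode: max base tariff, earliest wins ties (rows are sorted
  # by admission within spell, and which.max takes the first maximum)
  dom <- vapply(split(seq_along(grp), grp),
                function(ix) ix[which.max(base[ix])], integer(1))
  adm <- as.Date(vapply(split(as.numeric(episodes$admission_date), grp), min,
                        numeric(1)), origin = "1970-01-01")
  dis <- as.Date(vapply(split(as.numeric(episodes$discharge_date), grp), max,
                        numeric(1)), origin = "1970-01-01")
  los <- as.numeric(dis - adm)
  if (any(los < 0)) stop("validation error: negative spell length of stay")
  dom_hrg <- hrg[dom]
  dom_ti <- ti[dom]
  trim <- ifelse(is.na(dom_ti), Inf, tariffs$tariffs$trim_point[dom_ti])
  rate <- ifelse(is.na(dom_ti), 0, tariffs$tariffs$excess_rate[dom_ti])
  excess <- pmax(0, los - trim)
  nominal <- base[dom] + excess * rate
  all_opcs <- vapply(split(episodes$opcs_codes, grp), function(z) {
    z <- z[!is.na(z) & nzchar(z)]
    paste(unique(unlist(strsplit(z, "+", fixed = TRUE))), collapse = "+")
  }, character(1))
  out <- data.frame(
    patient_id = episodes$patient_id[dom],
    event_date = adm, discharge_date = dis,
    hrg_resolved = dom_hrg, los = los,
    excess_days = ifelse(is.finite(excess), excess, 0),
    nominal_cost = nominal,
    adjusted_cost = nominal * config$inflation_factor * config$mff,
    opcs_codes = all_opcs,
    source = "inpatient",
    stringsAsFactors = FALSE)
  attr(out, "n_unresolved") <- sum(is.na(dom_hrg))
  rownames(out) <- NULL
  out
}

#' Cost a single spell (convenience wrapper)
#'
#' @param spell data frame of the episodes of one spell.
#' @inheritParams cost_spells
#' @return one-row costed spell, as [cost_spells()].
#' @export
cost_spell <- function(spell, tariffs, config) {
  cost_spells(spell, tariffs, config)
}

#' Cost outpatient appointments
#'
#' Appointments with neither an oncology nor a gynaecology specialty (main or
#' treatment field) and no procedure code are excluded.  Among
#' oncology-specialty appointments, near-daily runs of at least
#' `radio_min_run` visits (gaps <= `radio_interval_max` days) are costed as
#' radiotherapy fractions; remaining runs of at least `chemo_min_run` visits
#' with gaps <= `chemo_interval_max` days are costed at the outpatient
#' chemotherapy tariff.  Both receive the inflation uplift and MFF.  All
#' other retained appointments are assigned the flat default outpatient cost
#' (already at 2012/13 prices, so MFF only).
#'
#' @param outpatient appointment data frame with `patient_id`, `date`,
#'   `main_specialty`, `treatment_specialty` and optional `opcs_codes`.
#' @inheritParams cost_spells
#' @return costed rows (excluded appointments dropped): `patient_id`,
#'   `event_date`, `hrg_resolved` (`"CHEMO"`/`"RADIO"` series tariff code or
#'   `NA` for the default cost), `series` flag, `nominal_cost`,
#'   `adjusted_cost`, `source`.
#' @export
cost_outpatient <- function(outpatient, tariffs, config) {
  if (nrow(outpatient) == 0L) return(data.frame())
  opcs <- if (is.null(outpatient$opcs_codes)) rep("", nrow(outpatient)) else
    ifelse(is.na(outpatient$opcs_codes), "", outpatient$opcs_codes)
  onc <- outpatient$main_specialty %in% config$oncology_specialties |
    outpatient$treatment_specialty %in% config$oncology_specialties
  gyn <- outpatient$main_specialty %in% config$gynae_specialties |
    outpatient$treatment_specialty %in% config$gynae_specialties
  keep <- onc | gyn | nzchar(opcs)
  outpatient <- outpatient[keep, , drop = FALSE]
  onc <- onc[keep]
  if (nrow(outpatient) == 0L) return(data.frame())
  o <- order(outpatient$patient_id, outpatient$date)
  outpatient <- outpatient[o, , drop = FALSE]
  onc <- onc[o]

  series <- rep(NA_character_, nrow(outpatient))
  for (ix in split(which(onc), outpatient$patient_id[onc])) {
    if (!length(ix)) next
    d <- as.numeric(outpatient$date[ix])
    # radiotherapy first: dense near-daily fraction runs
    run <- cumsum(c(TRUE, diff(d) > config$radio_interval_max))
    rl <- ave(run, run, FUN = length)
    is_radio <- rl >= config$radio_min_run
    series[ix[is_radio]] <- "radio"
    # chemotherapy: regular-interval runs among the rest
    rest <- which(!is_radio)
    if (length(rest)) {
      dr <- d[rest]
      run <- cumsum(c(TRUE, diff(dr) > config$chemo_interval_max))
      rl <- ave(run, run, FUN = length)
      series[ix[rest[rl >= config$chemo_min_run]]] <- "chemo"
    }
  }
  chemo_row <- tariffs$tariffs[tariffs$tariffs$setting == "outpatient" &
                               grepl("chemo", tariffs$tariffs$description,
                                     ignore.case = TRUE), ][1, ]
  radio_row <- tariffs$tariffs[tariffs$tariffs$setting == "outpatient" &
                               grepl("radio", tariffs$tariffs$description,
                                     ignore.case = TRUE), ][1, ]
  uplift <- config$inflation_factor * config$mff
  nominal <- ifelse(series %in% "chemo", chemo_row$base_tariff,
                    ifelse(series %in% "radio", radio_row$base_tariff,
                           config$default_outpatient_cost))
  adjusted <- ifelse(is.na(series),
                     config$default_outpatient_cost * config$mff,
                     nominal * uplift)
  data.frame(patient_id = outpatient$patient_id,
             event_date = outpatient$date,
             hrg_resolved = ifelse(series %in% "chemo", chemo_row$hrg,
                                   ifelse(series %in% "radio", radio_row$hrg,
                                          NA_character_)),
             series = series,
             los = 0, excess_days = 0,
             nominal_cost = nominal,
             adjusted_cost = adjusted,
             opcs_codes = opcs[keep][o],
             source = "outpatient",
             stringsAsFactors = FALSE)
}

#' Discount adjusted costs to the year of diagnosis
#'
#' Costs are assigned to annual bands anchored on the diagnosis-date
#' anniversary: band `k = floor(years since diagnosis)`, with pre-diagnostic
#' events in band 0.  Band 0 (the first year) is undiscounted; band `k` is
#' divided by `(1 + rate)^k`.
#'
#' @param adjusted_cost numeric vector of adjusted costs.
#' @param event_date,diagnosis_date `Date` vectors.
#' @param config a [costing_config()].
#' @return numeric vector of discounted costs.
#' @export
discount <- function(adjusted_cost, event_date, diagnosis_date, config) {
  yrs <- elapsed(diagnosis_date, event_date, "years")
  band <- pmax(0, floor(yrs))
  adjusted_cost / (1 + config$discount_rate)^band
}

#' Cost and classify a full event history
#'
#' Runs spell construction, spell and outpatient costing, discounting and
#' treatment-category classification for a cohort.  Categories: `surgery`
#' (hysterectomy/BSO spells plus any event before the surgery date — or
#' within the post-diagnosis grace window when no surgery occurred —
#' including pre-diagnostic investigations), `adjuvant` (chemo/radiotherapy
#' series events) and `further` (everything else).  Events outside the
#' half-open costing window `[-prediag_window, horizon)` are excluded and
#' counted in the `n_beyond_horizon` attribute.
#'
#' @param inpatient,outpatient activity tables (see [generate_episodes()]
#'   for schemas).
#' @param patients patient table with `patient_id` and `diagnosis_date`.
#' @inheritParams cost_spells
#' @return costed-event data frame with one row per spell or retained
#'   appointment: `patient_id`, `event_date`, `category`, `source`,
#'   `hrg_resolved`, `excess_days`, `nominal_cost`, `adjusted_cost`,
#'   `discounted_cost`.  Attributes `n_unresolved` and `n_beyond_horizon`
#'   carry engine diagnostics.
#' @export
cost_events <- function(inpatient, outpatient, patients, tariffs, config) {
  sp <- cost_spells(inpatient, tariffs, config)
  op <- cost_outpatient(outpatient, tariffs, config)
  common <- c("patient_id", "event_date", "hrg_resolved", "excess_days",
              "nominal_cost", "adjusted_cost", "opcs_codes", "source")
  ev <- rbind(
    if (nrow(sp)) cbind(sp[common], series = NA_character_) else NULL,
    if (nrow(op)) op[c(common, "series")] else NULL)
  if (is.null(ev) || nrow(ev) == 0L) {
    out <- data.frame()
    attr(out, "n_unresolved") <- 0L
    attr(out, "n_beyond_horizon") <- 0L
    return(out)
  }

  dxi <- match(ev$patient_id, patients$patient_id)
  if (anyNA(dxi)) stop("episode patient_id absent from patient table")
  dx <- patients$diagnosis_date[dxi]

  # costing window (half-open at the horizon)
  yrs <- elapsed(dx, ev$event_date, "years")
  in_window <- yrs >= -(config$prediag_window_months / 12) &
    yrs < config$horizon_years
  n_beyond <- sum(!in_window)
  ev <- ev[in_window, , drop = FALSE]
  dx <- dx[in_window]

  # surgery date per patient: earliest spell carrying a hysterectomy/BSO code
  is_surg_spell <- ev$source == "inpatient" &
    vapply(strsplit(ifelse(is.na(ev$opcs_codes), "", ev$opcs_codes), "+",
                    fixed = TRUE),
           function(z) any(z %in% c("Q07", "Q23")), logical(1))
  sdf <- ev[is_surg_spell, c("patient_id", "event_date")]
  surg_date <- if (nrow(sdf)) {
    tapply(as.numeric(sdf$event_date), sdf$patient_id, min)
  } else numeric(0)
  sd_i <- surg_date[ev$patient_id]
  cutoff_num <- ifelse(is.na(sd_i),
                       as.numeric(dx) + config$surgery_grace_days, sd_i)
  category <- ifelse(!is.na(ev$series), "adjuvant",
                     ifelse(is_surg_spell |
                              as.numeric(ev$event_date) <= cutoff_num,
                            "surgery", "further"))
  ev$category <- factor(category, levels = c("surgery", "adjuvant", "further"))
  ev$discounted_cost <- discount(ev$adjusted_cost, ev$event_date, dx, config)
  ev$series <- NULL
  ev <- ev[order(ev$patient_id, ev$event_date), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "n_unresolved") <- attr(sp, "n_unresolved")
  attr(ev, "n_beyond_horizon") <- n_beyond
  ev
}

#' Per-patient category costs at a horizon
#'
#' @param events costed events from [cost_events()].
#' @param patients patient table (provides diagnosis dates; patients with no
#'   events receive zero rows only if present in `events`).
#' @param horizon_years horizon (half-open) at which to accumulate
#'   discounted costs.
#' @return data frame `patient_id`, `surgery`, `adjuvant`, `further`,
#'   `total`.
#' @export
patient_costs <- function(events, patients, horizon_years = 5) {
  if (nrow(events) == 0L) {
    return(data.frame(patient_id = character(0), surgery = numeric(0),
                      adjuvant = numeric(0), further = numeric(0),
                      total = numeric(0)))
  }
  dx <- patients$diagnosis_date[match(events$patient_id, patients$patient_id)]
  keep <- !is.na(dx) & elapsed(dx, events$event_date, "years") < horizon_years
  ev <- events[keep, , drop = FALSE]
  m <- tapply(ev$discounted_cost, list(ev$patient_id, ev$category), sum,
              default = 0)
  out <- data.frame(patient_id = rownames(m),
                    surgery = m[, "surgery"], adjuvant = m[, "adjuvant"],
                    further = m[, "further"], stringsAsFactors = FALSE)
  out$total <- out$surgery + out$adjuvant + out$further
  rownames(out) <- NULL
  out
}

#' Build monthly cumulative cost trajectories
#'
#' Cumulative discounted cost per patient sampled at month indices -6 to +60
#' relative to diagnosis (30.4375-day months), with per-category
#' sub-trajectories.  A patient's `censor_month` is the month index of the
#' administrative cutoff when cost follow-up is incomplete, `NA` otherwise.
#'
#' @param events costed events from [cost_events()].
#' @param patients patient table; a `cost_censored` logical column (set by
#'   [apply_administrative_censoring()]) and `cutoff` drive `censor_month`.
#' @param config a [costing_config()].
#' @param cutoff administrative cutoff date, or `NULL` for fully observed
#'   data.
#' @return object of class `"stagecost_trajectories"`: list with `months`
#'   (-6:60), `total` (patients x months cumulative-cost matrix), `category`
#'   (3-slice list of matrices), `patients`, `stage`, `censor_month`.
#' @export
build_trajectories <- function(events, patients, config = costing_config(),
                               cutoff = NULL) {
  months <- -6:60
  n <- nrow(patients)
  mk <- function() matrix(0, n, length(months),
                          dimnames = list(patients$patient_id, months))
  total <- mk()
  cats <- list(surgery = mk(), adjuvant = mk(), further = mk())
  if (nrow(events)) {
    pi <- match(events$patient_id, patients$patient_id)
    em <- elapsed(patients$diagnosis_date[pi], events$event_date, "months")
    # cumulative at month m includes events up to and including m
    col <- findInterval(em, months, left.open = TRUE) + 1L
    col <- pmin(pmax(col, 1L), length(months))
    for (cat in levels(events$category)) {
      sel <- events$category == cat
      if (!any(sel)) next
      inc <- mk()
      idx <- cbind(pi[sel], col[sel])
      agg <- tapply(events$discounted_cost[sel],
                    list(idx[, 1], idx[, 2]), sum)
      ij <- which(!is.na(agg), arr.ind = TRUE)
      inc[cbind(as.integer(rownames(agg))[ij[, 1]],
                as.integer(colnames(agg))[ij[, 2]])] <- agg[ij]
      cm <- t(apply(inc, 1, cumsum))
      cats[[cat]] <- cm
      total <- total + cm
    }
  }
  censor_month <- rep(NA_real_, n)
  if (!is.null(cutoff)) {
    cm <- elapsed(patients$diagnosis_date, cutoff, "months")
    flag <- if (!is.null(patients$cost_censored)) patients$cost_censored else
      cm < 60
    censor_month[flag] <- pmin(cm[flag], 60)
  }
  structure(list(months = months, total = total, category = cats,
                 patients = patients$patient_id,
                 stage = patients$stage,
                 censor_month = censor_month),
            class = "stagecost_trajectories")
}
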