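#' Costing configuration
#'
#' Bundles the tariff-adjustment and discounting constants used by the cost
#' engine.  Defaults follow standard English NHS costing practice for the
#' study period: 2005 casemix (HRG v3.5) base tariffs uplifted to 2012/13
#' prices, an average Market Forces Factor of 1.08, a flat outpatient cost of
#' 135 GBP (already at 2012/13 prices, so it receives the MFF only), and
#' annual discounting at 3.5% for costs beyond the first year after
#' diagnosis.
#'
#' @param mff market forces factor multiplier applied to every cost.
#' @param inflation_factor hospital price-index uplift from the 2005 tariff
#'   base to 2012/13 prices; applied to tariff-derived costs only.
#' @param default_outpatient_cost flat cost (GBP, 2012/13) for retained
#'   outpatient appointments not part of a chemo/radiotherapy series.
#' @param discount_rate annual discount rate; year band 0 (the first year
#'   after diagnosis, including the pre-diagnostic window) is undiscounted.
#' @param prediag_window_months months before diagnosis within which
#'   investigations are costed.
#' @param horizon_years costing horizon after diagnosis (half-open: an event
#'   on the anniversary day is excluded).
#' @param chemo_interval_max maximum gap in days between successive oncology
#'   appointments within one chemotherapy series.
#' @param chemo_min_run minimum number of appointments forming a
#'   chemotherapy series.
#' @param radio_interval_max maximum gap in days between successive fractions
#'   of a radiotherapy course (near-daily attendance).
#' @param radio_min_run minimum number of fractions forming a radiotherapy
#'   course.
#' @param oncology_specialties,gynae_specialties specialty labels used for
#'   outpatient inclusion and series detection.
#' @param surgery_grace_days for patients without a hysterectomy/BSO spell,
#'   events within this many days of diagnosis count as diagnosis/surgery
#'   work-up when classifying cost categories.
#' @return a list of class `"stagecost_config"`.
#' @export
costing_config <- function(mff = 1.08,
                           inflation_factor = 1.20,
                           default_outpatient_cost = 135,
                           discount_rate = 0.035,
                           prediag_window_months = 6,
                           horizon_years = 5,
                           chemo_interval_max = 35,
                           chemo_min_run = 3,
                           radio_interval_max = 3,
                           radio_min_run = 5,
                           oncology_specialties = c("medical_oncology",
                                                    "clinical_oncology"),
                           gynae_specialties = "gynaecology",
                           surgery_grace_days = 42) {
  stopifnot(mff > 0, inflation_factor > 0,
            discount_rate >= 0, discount_rate < 1,
            horizon_years > 0, prediag_window_months >= 0)
  structure(list(
    mff = mff,
    inflation_factor = inflation_factor,
    default_outpatient_cost = default_outpatient_cost,
    discount_rate = discount_rate,
    prediag_window_months = prediag_window_months,
    horizon_years = horizon_years,
    chemo_interval_max = chemo_interval_max,
    chemo_min_run = chemo_min_run,
    radio_interval_max = radio_interval_max,
    radio_min_run = radio_min_run,
    oncology_specialties = oncology_specialties,
    gynae_specialties = gynae_specialties,
    surgery_grace_days = surgery_grace_days
  ), class = "stagecost_config")
}

#' Load a tariff table
#'
#' A tariff table holds, per HRG code: the base tariff (2005 price base for
#' inpatient HRGs), the trim point (maximum length of stay the tariff
#' covers), the excess-bed-day rate payable per day beyond the trim point,
#' and the care setting.  An OPCS-to-HRG fallback map resolves episodes whose
#' HRG field is blank.  The packaged table is a small synthetic stand-in for
#' the national tariff database, sufficient for the codes the generator
#' emits; supply your own file for real data.
#'
#' @param file path to a CSV with columns `hrg, description, setting,
#'   base_tariff, trim_point, excess_rate`.
#' @param opcs_map_file path to a CSV with columns `opcs, hrg`.
#' @return a list of class `"stagecost_tariffs"` with elements `tariffs`
#'   (data frame) and `opcs_map` (named character vector).
#' @export
load_tariffs <- function(file = system.file("extdata", "tariffs_synthetic.csv",
                                            package = "stagecost"),
                         opcs_map_file = system.file("extdata",
                                                     "opcs_hrg_map.csv",
                                                     package = "stagecost")) {
  tar <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("hrg", "setting", "base_tariff", "trim_point", "excess_rate")
  if (!all(need %in% names(tar))) {
    stop("tariff file must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(tar) == 0L) stop("tariff table is empty")
  if (any(tar$base_tariff < 0) || any(tar$excess_rate < 0)) {
    stop("tariffs and excess-bed-day rates must be non-negative")
  }
  if (any(tar$trim_point < 1)) stop("trim points must be >= 1 day")
  if (anyDuplicated(tar$hrg)) stop("duplicate HRG codes in tariff table")
  map <- read.csv(opcs_map_file, stringsAsFactors = FALSE)
  opcs_map <- setNames(map$hrg, map$opcs)
  unknown <- setdiff(opcs_map, tar$hrg)
  if (length(unknown)) {
    stop("OPCS map targets HRG codes absent from the tariff table: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(tariffs = tar, opcs_map = opcs_map),
            class = "stagecost_tariffs")
}

#' @rdname load_tariffs
#' @export
default_tariffs <- function() load_tariffs()

tariff_row <- function(tariffs, hrg) {
  i <- match(hrg, tariffs$tariffs$hrg)
  tariffs$tariffs[i, , drop = FALSE]
}
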