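#' Flag endometrial-cancer notifications
#'
#' Keeps records whose notification diagnosis code begins with ICD-10 C54
#' (malignant neoplasm of corpus uteri) or C55 (uterus, part unspecified);
#' everything else is dropped with a logged count.
#'
#' @param records data frame with a `notified_icd10` column.
#' @param code_col name of the diagnosis-code column.
#' @return the flagged subset, with attribute `n_dropped`.
#' @export
identify_ec_notifications <- function(records, code_col = "notified_icd10") {
  if (nrow(records) == 0L) {
    warning("empty notification input")
    out <- records
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  code <- gsub("\\.", "", toupper(trimws(records[[code_col]])))
  keep <- grepl("^C5[45]", code)
  out <- records[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  rownames(out) <- NULL
  out
}

#' Apply the exclusion cascade
#'
#' Exclusions are applied in a fixed order — clinical review outcome (other
#' primary or synchronous endometrial + ovarian/peritoneal cancer), then
#' incomplete hospital-activity data (case notes record surgery but no
#' hysterectomy/BSO procedure code in any inpatient episode), then missing
#' stage — and a candidate matching several reasons is counted once, under
#' the earliest.
#'
#' @param candidates data frame with logical columns `review_excluded` and
#'   `hes_incomplete`, and a `stage` column (`NA` = missing).
#' @return list with `cohort` (included rows, `exclusion_reason = "none"`)
#'   and `report`, an `ExclusionReport`-style list
#'   (`n_notified`, `n_excluded_by_reason`, `n_included`).
#' @export
apply_exclusions <- function(candidates) {
  rev_x <- isTRUE_vec(candidates$review_excluded)
  hes_x <- !rev_x & isTRUE_vec(candidates$hes_incomplete)
  stage_x <- !rev_x & !hes_x & is.na(candidates$stage)
  reason <- rep("none", nrow(candidates))
  reason[stage_x] <- "missing_stage"
  reason[hes_x] <- "incomplete_HES"
  reason[rev_x] <- "not_EC_or_synchronous"
  candidates$exclusion_reason <- reason
  cohort <- candidates[reason == "none", , drop = FALSE]
  rownames(cohort) <- NULL
  report <- list(
    n_notified = nrow(candidates),
    n_excluded_by_reason = c(
      not_EC_or_synchronous = sum(rev_x),
      incomplete_HES = sum(hes_x),
      missing_stage = sum(stage_x)),
    n_included = nrow(cohort))
  stopifnot(report$n_included + sum(report$n_excluded_by_reason) ==
              report$n_notified)
  list(cohort = cohort, report = report)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Load the Charlson ICD-10 weight map
#'
#' The packaged map implements the Quan et al. ICD-10 coding of the Charlson
#' conditions with the original weights; malignancy/metastasis rows are
#' flagged so they can be excluded when scoring cancer cohorts.
#'
#' @param file CSV with columns `prefix, condition, weight, malignancy`.
#' @return data frame, longest prefixes first.
#' @export
charlson_map <- function(file = system.file("extdata", "charlson_icd10.csv",
                                            package = "stagecost")) {
  map <- read.csv(file, stringsAsFactors = FALSE)
  map[order(-nchar(map$prefix)), ]
}

#' Charlson comorbidity score from ICD-10 codes
#'
#' Scores a set of ICD-10 codes with the standard weights, after excluding
#' all malignancy and metastasis items (appropriate when every patient
#' carries the index cancer).  Within the diabetes and liver-disease
#' hierarchies only the more severe form counts.
#'
#' @param icd_codes character vector of ICD-10 codes (dots ignored), or a
#'   single `"+"`-separated string.
#' @param map a [charlson_map()] data frame.
#' @param exclude_malignancy drop cancer/metastasis items before scoring.
#' @return a non-negative integer score.
#' @export
compute_charlson <- function(icd_codes, map = charlson_map(),
                             exclude_malignancy = TRUE) {
  codes <- unlist(strsplit(icd_codes, "+", fixed = TRUE))
  codes <- gsub("\\.", "", toupper(trimws(codes)))
  codes <- codes[nzchar(codes)]
  if (!length(codes)) return(0L)
  if (exclude_malignancy) map <- map[map$malignancy == 0, , drop = FALSE]
  hit <- vapply(codes, function(cd) {
    i <- which(startsWith(cd, map$prefix))
    if (length(i)) i[1] else NA_integer_  # map sorted longest-prefix-first
  }, integer(1))
  hit <- hit[!is.na(hit)]
  if (!length(hit)) return(0L)
  cond <- unique(map$condition[hit])
  w <- map$weight[match(cond, map$condition)]
  names(w) <- cond
  for (pair in list(c("diab", "diab_comp"), c("liver_mild", "liver_severe"),
                    c("malignancy", "metastasis"))) {
    if (all(pair %in% cond)) w <- w[names(w) != pair[1]]
  }
  as.integer(sum(w))
}

#' Derive patient-level covariates and assemble the analysis cohort
#'
#' Recomputes the Charlson score from the ICD-10 codes of the
#' hysterectomy/BSO episode (or, absent one, the first inpatient episode
#' after diagnosis; patients with neither score 0), classifies BMI
#' (under 18.5 / 18.5-30 / over 30), and derives the diagnosis-year
#' covariate as whole years since the cohort's earliest diagnosis month
#' (January 2002 by default).  Exclusion flags, if present, are applied via
#' [apply_exclusions()].
#'
#' @param patients patient table.
#' @param inpatient inpatient episode table (for Charlson derivation).
#' @param map Charlson weight map.
#' @param year_origin anchor date for the diagnosis-year covariate.
#' @return list with `cohort` (covariate-augmented included patients) and
#'   `report` (exclusion report).
#' @export
assemble_cohort <- function(patients, inpatient, map = charlson_map(),
                            year_origin = as.Date("2002-01-01")) {
  patients <- identify_ec_notifications(patients)
  n_dropped <- attr(patients, "n_dropped")
  surg_opcs <- c("Q07", "Q23")
  ch <- vapply(seq_len(nrow(patients)), function(i) {
    eps <- inpatient[inpatient$patient_id == patients$patient_id[i] &
                       inpatient$admission_date >= patients$diagnosis_date[i], ,
                     drop = FALSE]
    if (nrow(eps) == 0L) return(0L)
    has_surg <- vapply(strsplit(ifelse(is.na(eps$opcs_codes), "",
                                       eps$opcs_codes), "+", fixed = TRUE),
                       function(z) any(z %in% surg_opcs), logical(1))
    pick <- if (any(has_surg)) which(has_surg)[1] else
      which.min(eps$admission_date)
    compute_charlson(eps$icd10_codes[pick], map)
  }, integer(1))
  patients$charlson_derived <- ch
  patients$bmi_class <- cut(patients$bmi, c(-Inf, 18.5, 30, Inf),
                            labels = c("under_18_5", "18_5_to_30", "over_30"),
                            right = TRUE)
  patients$diagnosis_year <- floor(elapsed(year_origin,
                                           patients$diagnosis_date, "years"))
  res <- apply_exclusions(patients)
  res$report$n_not_ec_code <- n_dropped
  res
}
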