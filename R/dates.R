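#' Snap a year-month to the 15th of the month
#'
#' Dates of birth and death are held at month precision for confidentiality;
#' each is arbitrarily assigned to the 15th of the relevant month before any
#' interval arithmetic.
#'
#' @param x a `Date` vector, or a character vector in `"YYYY-MM"` or
#'   `"YYYY-MM-DD"` form.
#' @return a `Date` vector with day of month 15; `NA` elements pass through.
#' @examples
#' snap_to_midmonth("2005-07")        # 2005-07-15
#' snap_to_midmonth(as.Date("2010-02-03"))
#' @export
snap_to_midmonth <- function(x) {
  if (is.character(x)) {
    x <- trimws(x)
    ym <- grepl("^\\d{4}-\\d{2}$", x)
    bad <- !is.na(x) & !ym & !grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
    if (any(bad)) {
      stop("cannot parse year-month value(s): ",
           paste(unique(x[bad]), collapse = ", "))
    }
    x[ym & !is.na(x)] <- paste0(x[ym & !is.na(x)], "-01")
    x <- as.Date(x)
  }
  if (!inherits(x, "Date")) stop("'x' must be a Date or character vector")
  out <- as.Date(format(x, "%Y-%m-15"))
  out[is.na(x)] <- as.Date(NA)
  out
}

# average-month length used for month-index arithmetic throughout
DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25

#' Elapsed time between two dates
#'
#' @param from,to `Date` vectors.
#' @param unit `"days"`, `"months"` (30.4375-day months) or `"years"`
#'   (365.25-day years).
#' @return numeric vector of elapsed time.
#' @keywords internal
elapsed <- function(from, to, unit = c("years", "months", "days")) {
  unit <- match.arg(unit)
  d <- as.numeric(to - from)
  switch(unit, days = d, months = d / DAYS_PER_MONTH, years = d / DAYS_PER_YEAR)
}
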