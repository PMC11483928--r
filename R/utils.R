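`%||%` <- function(a, b) if (is.null(a)) b else a

# locale-independent sort for regimen labels and drug codes
sort_c <- function(x) sort(x, method = "radix")

#' Normalize a diagnosis or drug code
#'
#' Uppercases and strips dots and whitespace so that "L40.1", "l401" and
#' " L40.1 " compare equal.  Used for every ICD-10 comparison in the package.
#'
#' @param x character vector of codes.
#' @return character vector of normalized codes.
#' @export
normalize_code <- function(x) gsub("[. ]", "", toupper(trimws(as.character(x))))

#' Convert day counts to months
#'
#' Single day-to-month conversion used throughout the package.  All internal
#' arithmetic is in integer days; months appear only at reporting.  The month
#' length defaults to 30.4375 days (Julian year / 12).
#'
#' @param days non-negative numeric vector of day counts.
#' @param month_length_days days per month (default 30.4375).
#' @return numeric vector of months.
#' @examples
#' months_from_days(365.25)  # 12
#' @export
months_from_days <- function(days, month_length_days = 30.4375) {
  if (any(days < 0, na.rm = TRUE)) {
    stop("months_from_days(): negative day counts are not allowed")
  }
  days / month_length_days
}

# integer day difference b - a for Date vectors
days_between <- function(a, b) as.integer(as.integer(b) - as.integer(a))

as_date_safe <- function(x) {
  # strict ISO-8601 parse; returns NA for anything unparseable
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  chr <- trimws(as.character(x))
  ok <- !is.na(chr) & chr != ""
  if (any(ok)) {
    parsed <- as.Date(chr[ok], format = "%Y-%m-%d")
    # reject partial garbage that as.Date tolerates (e.g. "2020-1-")
    bad <- !is.na(parsed) & format(parsed, "%Y-%m-%d") != chr[ok]
    parsed[bad] <- NA
    out[ok] <- parsed
  }
  out
}
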