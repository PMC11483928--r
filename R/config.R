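#' Analysis configuration
#'
#' Collects every tunable convention of the pipeline in one list.  Defaults
#' encode the study conventions: enrolment window 2016-01-01 to 2021-08-31,
#' a 30.4375-day month, discontinuation gaps of 3 months for biologics and
#' 2 months for oral (and other non-biologic) drugs, a 30-day combination
#' window for treating near-simultaneous starts as one combination line, a
#' 365-day baseline period and a required follow-up strictly greater than
#' 365 days (waived for patients who died within that first year).
#'
#' @param study_start,study_end study window (Date or ISO-8601 string).
#' @param month_length_days days per reported month; 30.4375 = 365.25 / 12.
#' @param gap_months named numeric: discontinuation gap, in months, per gap
#'   class (`biologic`, `oral`, `other`).  Rounded to whole days when applied.
#' @param gap_overrides optional named integer vector of per-drug gap
#'   thresholds in days (names are drug codes); overrides the class gap.
#' @param combination_window_days a main drug starting within this many days
#'   of the current line's start joins it as a combination.
#' @param baseline_days length of the pre-index baseline period.
#' @param min_followup_days patients followed for <= this many days after the
#'   index date are excluded unless they died within that span.
#' @param date_slack_days validation slack: record dates may precede the
#'   study start (baseline claims) or trail its end by at most this much.
#' @param stockpile if `TRUE`, overlapping coverage is carried forward
#'   (stockpiling); default `FALSE` truncates overlap.
#' @param min_supp_lot_days minimum length, in days, of a supplementary-only
#'   period for it to count as its own line of therapy.
#' @param psv_baseline_only if `TRUE` the psoriasis-vulgaris flag uses
#'   baseline diagnoses only; default uses the whole record.
#' @param apheresis_dominates if `TRUE`, apheresis/plasma exchange labels the
#'   general regimen of any combination containing it, overriding strict
#'   priority order.
#' @param censor_last_policy `"always"`: a patient's last episode of a drug
#'   (and last line of therapy) is always censored; `"near_followup"`: the
#'   last episode is censored only when it ends within its gap threshold of
#'   the end of follow-up, otherwise counted as an event.
#' @param duration_basis basis for the >1-year / >2-year on-drug proportions:
#'   `"cumulative"` per-patient days on drug, or `"longest"` single episode.
#' @param strict_drug_codes if `TRUE`, unknown drug codes are an error rather
#'   than falling back to the supplementary "Other oral medications" class.
#' @param gpp_code,psv_code diagnosis codes for GPP and psoriasis vulgaris.
#' @return a list of class `journey_config`.
#' @export
journey_config <- function(study_start = "2016-01-01",
                           study_end = "2021-08-31",
                           month_length_days = 30.4375,
                           gap_months = c(biologic = 3, oral = 2, other = 2),
                           gap_overrides = NULL,
                           combination_window_days = 30L,
                           baseline_days = 365L,
                           min_followup_days = 365L,
                           date_slack_days = 730L,
                           stockpile = FALSE,
                           min_supp_lot_days = 1L,
                           psv_baseline_only = FALSE,
                           apheresis_dominates = FALSE,
                           censor_last_policy = c("always", "near_followup"),
                           duration_basis = c("cumulative", "longest"),
                           strict_drug_codes = FALSE,
                           gpp_code = "L40.1",
                           psv_code = "L40.0") {
  stopifnot(month_length_days > 0, combination_window_days >= 0)
  cfg <- list(
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    month_length_days = month_length_days,
    gap_months = gap_months,
    gap_overrides = gap_overrides,
    combination_window_days = as.integer(combination_window_days),
    baseline_days = as.integer(baseline_days),
    min_followup_days = as.integer(min_followup_days),
    date_slack_days = as.integer(date_slack_days),
    stockpile = isTRUE(stockpile),
    min_supp_lot_days = as.integer(min_supp_lot_days),
    psv_baseline_only = isTRUE(psv_baseline_only),
    apheresis_dominates = isTRUE(apheresis_dominates),
    censor_last_policy = match.arg(censor_last_policy),
    duration_basis = match.arg(duration_basis),
    strict_drug_codes = isTRUE(strict_drug_codes),
    gpp_code = gpp_code,
    psv_code = psv_code
  )
  if (cfg$study_end <= cfg$study_start) stop("study_end must follow study_start")
  class(cfg) <- "journey_config"
  cfg
}

#' Read a configuration from a YAML file
#'
#' Keys absent from the file keep their [journey_config()] defaults.
#'
#' @param path YAML file path.
#' @return a `journey_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(journey_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(vals$gap_months)) vals$gap_months <- unlist(vals$gap_months)
  if (!is.null(vals$gap_overrides)) vals$gap_overrides <- unlist(vals$gap_overrides)
  do.call(journey_config, vals)
}

#' @export
print.journey_config <- function(x, ...) {
  cat("journey_config\n")
  cat("  study window:        ", format(x$study_start), "to", format(x$study_end), "\n")
  cat("  month length (days): ", x$month_length_days, "\n")
  cat("  gaps (months):       ",
      paste(names(x$gap_months), x$gap_months, sep = "=", collapse = ", "), "\n")
  cat("  combination window:  ", x$combination_window_days, "days\n")
  invisible(x)
}
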