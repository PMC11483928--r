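# Quan (2005) ICD-10 coding algorithm for the 17 Charlson condition groups,
# scored with the original Charlson weights.  Codes are matched by prefix on
# normalized (dot-free, uppercase) ICD-10 codes.
.cci_cache <- new.env(parent = emptyenv())

quan_cci_map <- function() {
  if (!is.null(.cci_cache$map)) return(.cci_cache$map)
  .cci_cache$map <- build_quan_cci_map()
  .cci_cache$map
}

build_quan_cci_map <- function() {
  g <- function(condition, weight, prefixes) {
    data.frame(condition = condition, weight = weight, prefix = prefixes,
               stringsAsFactors = FALSE)
  }
  rbind(
    g("myocardial_infarction", 1L, c("I21", "I22", "I252")),
    g("congestive_heart_failure", 1L,
      c("I099", "I110", "I130", "I132", "I255", "I420", "I425", "I426",
        "I427", "I428", "I429", "I43", "I50", "P290")),
    g("peripheral_vascular", 1L,
      c("I70", "I71", "I731", "I738", "I739", "I771", "I790", "I792",
        "K551", "K558", "K559", "Z958", "Z959")),
    g("cerebrovascular", 1L,
      c("G45", "G46", "H340", paste0("I6", 0:9))),
    g("dementia", 1L, c("F00", "F01", "F02", "F03", "F051", "G30", "G311")),
    g("chronic_pulmonary", 1L,
      c("I278", "I279", paste0("J4", 0:7), paste0("J6", 0:7), "J684",
        "J701", "J703")),
    g("rheumatic", 1L,
      c("M05", "M06", "M315", "M32", "M33", "M34", "M351", "M353", "M360")),
    g("peptic_ulcer", 1L, c("K25", "K26", "K27", "K28")),
    g("mild_liver", 1L,
      c("B18", "K700", "K701", "K702", "K703", "K709", "K713", "K714",
        "K715", "K717", "K73", "K74", "K760", "K762", "K763", "K764",
        "K768", "K769", "Z944")),
    g("diabetes_uncomplicated", 1L,
      paste0("E1", rep(0:4, each = 5), rep(c(0, 1, 6, 8, 9), times = 5))),
    g("diabetes_complicated", 2L,
      paste0("E1", rep(0:4, each = 5), rep(c(2, 3, 4, 5, 7), times = 5))),
    g("hemiplegia_paraplegia", 2L,
      c("G041", "G114", "G801", "G802", "G81", "G82", "G830", "G831",
        "G832", "G833", "G834", "G839")),
    g("renal", 2L,
      c("I120", "I131", paste0("N03", 2:7), paste0("N05", 2:7), "N18",
        "N19", "N250", "Z490", "Z491", "Z492", "Z940", "Z992")),
    g("malignancy", 2L,
      c(sprintf("C%02d", c(0:26, 30:34, 37:41, 43, 45:58, 60:76)),
        "C81", "C82", "C83", "C84", "C85", "C88",
        paste0("C9", 0:7))),
    g("severe_liver", 3L,
      c("I850", "I859", "I864", "I982", "K704", "K711", "K721", "K729",
        "K765", "K766", "K767")),
    g("metastatic_cancer", 6L, c("C77", "C78", "C79", "C80")),
    g("aids_hiv", 6L, c("B20", "B21", "B22", "B24"))
  )
}

#' Charlson comorbidity index (Quan ICD-10 coding)
#'
#' Maps ICD-10 codes onto the 17 Charlson condition groups using Quan's
#' coding algorithm and sums the original Charlson weights, counting each
#' condition at most once.  Hierarchy rules: metastatic cancer (weight 6)
#' supersedes any malignancy (2); moderate/severe liver disease (3)
#' supersedes mild liver disease (1); complicated diabetes (2) supersedes
#' uncomplicated diabetes (1).
#'
#' @param codes character vector of ICD-10 codes (dots allowed), typically
#'   the patient's baseline-window diagnoses.
#' @return a single non-negative integer score.
#' @export
compute_cci_quan <- function(codes) {
  if (length(codes) == 0) return(0L)
  codes <- normalize_code(codes)
  map <- quan_cci_map()
  hit <- vapply(split(map$prefix, map$condition), function(prefixes) {
    any(outer(codes, prefixes, startsWith))
  }, logical(1))
  weights <- setNames(map$weight[!duplicated(map$condition)],
                      map$condition[!duplicated(map$condition)])
  weights <- weights[names(hit)]
  if (hit[["metastatic_cancer"]]) hit[["malignancy"]] <- FALSE
  if (hit[["severe_liver"]]) hit[["mild_liver"]] <- FALSE
  if (hit[["diabetes_complicated"]]) hit[["diabetes_uncomplicated"]] <- FALSE
  as.integer(sum(weights[hit]))
}

#' Index date of a patient
#'
#' The index date is the earliest confirmed GPP diagnosis (code L40.1 by
#' default) within the study enrolment window; `NA` when the patient has no
#' such diagnosis.  Invariant to record order.
#'
#' @param diagnoses diagnosis rows of one patient.
#' @param config a [journey_config()].
#' @return a `Date`, or `NA` if no confirmed in-window GPP diagnosis exists.
#' @export
determine_index_date <- function(diagnoses, config = journey_config()) {
  if (nrow(diagnoses) == 0) return(as.Date(NA))
  gpp <- normalize_code(diagnoses$code) == normalize_code(config$gpp_code)
  ok <- gpp & diagnoses$confirmed &
    diagnoses$date >= config$study_start & diagnoses$date <= config$study_end
  if (!any(ok)) return(as.Date(NA))
  min(diagnoses$date[ok])
}

#' Eligibility decision for one patient
#'
#' Applies the cohort rules: patients are excluded when they have no
#' confirmed in-window GPP diagnosis (`unclear_history`), when they have
#' only one confirmed GPP diagnosis counted by distinct service date
#' (`single_gpp_diagnosis`), or when they could not be followed for more
#' than `min_followup_days` after the index date — unless they died within
#' that span (`insufficient_followup`).  Follow-up ends at the earliest of
#' study end, death, and last recorded claim activity.
#'
#' @param patient one row of the patients table.
#' @param diagnoses,prescriptions this patient's rows.
#' @param config a [journey_config()].
#' @return a one-row data.frame: `patient_id, included, reason, index_date,`
#'   `followup_end`.
#' @export
apply_eligibility <- function(patient, diagnoses, prescriptions,
                              config = journey_config()) {
  decide <- function(included, reason, index = as.Date(NA),
                     fend = as.Date(NA)) {
    data.frame(patient_id = patient$patient_id, included = included,
               reason = reason, index_date = index, followup_end = fend,
               stringsAsFactors = FALSE)
  }
  index <- determine_index_date(diagnoses, config)
  if (is.na(index)) return(decide(FALSE, "unclear_history"))

  gpp <- normalize_code(diagnoses$code) == normalize_code(config$gpp_code)
  gpp_dates <- unique(diagnoses$date[gpp & diagnoses$confirmed])
  if (length(gpp_dates) < 2L) {
    return(decide(FALSE, "single_gpp_diagnosis", index))
  }

  last_activity <- suppressWarnings(
    max(c(diagnoses$date, prescriptions$date), na.rm = TRUE))
  fend <- min(c(config$study_end, patient$death_date, last_activity),
              na.rm = TRUE)
  followed <- days_between(index, fend)
  died_within <- !is.na(patient$death_date) &&
    days_between(index, patient$death_date) <= config$min_followup_days
  if (followed <= config$min_followup_days && !died_within) {
    return(decide(FALSE, "insufficient_followup", index, fend))
  }
  decide(TRUE, "ok", index, fend)
}

#' Subgroup flags for a cohort patient
#'
#' The psoriasis-vulgaris flag is true when any confirmed L40.0 (or the
#' configured local code) appears anywhere in the record — or baseline only
#' when `config$psv_baseline_only` — and the age flags use age at index
#' with inclusive thresholds (65 and 75 years).
#'
#' @param patient one cohort row (needs `index_date`, `age_at_index`).
#' @param diagnoses this patient's diagnosis rows.
#' @param config a [journey_config()].
#' @return a one-row data.frame: `has_psv, age_ge65, age_ge75`.
#' @export
assign_subgroups <- function(patient, diagnoses, config = journey_config()) {
  psv <- normalize_code(diagnoses$code) == normalize_code(config$psv_code) &
    diagnoses$confirmed
  if (config$psv_baseline_only) {
    psv <- psv & diagnoses$date < patient$index_date &
      diagnoses$date >= patient$index_date - config$baseline_days
  }
  data.frame(has_psv = any(psv),
             age_ge65 = patient$age_at_index >= 65,
             age_ge75 = patient$age_at_index >= 75)
}

#' Build the analysis cohort
#'
#' Applies eligibility to every patient in the bundle (each patient receives
#' exactly one decision), then computes, for included patients, age at
#' index, the Quan/Charlson comorbidity score over the one-year baseline
#' window `[index - 365 days, index)`, and subgroup flags.
#'
#' @param bundle a `claims_bundle`.
#' @param config a [journey_config()].
#' @return a data.frame with one row per bundle patient:
#'   `patient_id, included, reason, index_date, followup_end, age_at_index,`
#'   `cci_score, has_psv, age_ge65, age_ge75`.
#' @export
build_cohort <- function(bundle, config = journey_config()) {
  stopifnot(inherits(bundle, "claims_bundle"))
  pat <- bundle$patients
  dx_by <- split(bundle$diagnoses, bundle$diagnoses$patient_id)
  rx_by <- split(bundle$prescriptions, bundle$prescriptions$patient_id)
  empty_dx <- bundle$diagnoses[0, ]
  empty_rx <- bundle$prescriptions[0, ]

  rows <- lapply(seq_len(nrow(pat)), function(i) {
    p <- pat[i, ]
    dx <- dx_by[[p$patient_id]] %||% empty_dx
    rx <- rx_by[[p$patient_id]] %||% empty_rx
    dec <- apply_eligibility(p, dx, rx, config)
    if (!dec$included) {
      dec$age_at_index <- NA_integer_
      dec$cci_score <- NA_integer_
      dec$has_psv <- NA
      dec$age_ge65 <- NA
      dec$age_ge75 <- NA
      return(dec)
    }
    dec$age_at_index <-
      as.integer(format(dec$index_date, "%Y")) - p$birth_year
    base_lo <- dec$index_date - config$baseline_days
    in_base <- dx$date >= base_lo & dx$date < dec$index_date & dx$confirmed
    dec$cci_score <- compute_cci_quan(dx$code[in_base])
    cbind(dec, assign_subgroups(dec, dx, config))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, method = "radix"), ]
  rownames(out) <- NULL
  out
}
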