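#' Construct a claims bundle
#'
#' A claims bundle is the raw input of the pipeline: a patients table
#' (`patient_id, sex, birth_year, death_date`), a diagnoses table
#' (`patient_id, code, date, confirmed`) and a prescriptions table
#' (`patient_id, drug_code, date, days_supply`), plus the study window.
#' All dates are calendar dates (class `Date`); intervals everywhere in the
#' package are half-open `[start, end)`.
#'
#' @param patients,diagnoses,prescriptions data.frames with the columns
#'   above.  `death_date` and `days_supply` may be `NA`; a missing
#'   `confirmed` column defaults to `TRUE` (sources without a
#'   suspected-diagnosis flag).
#' @param study_window length-2 Date vector `c(start, end)`.
#' @param parse_errors optional data.frame of row-level errors collected
#'   while reading (kept with the bundle so bad rows are auditable, never
#'   silently dropped).
#' @return an object of class `claims_bundle`.
#' @export
claims_bundle <- function(patients, diagnoses, prescriptions, study_window,
                          parse_errors = NULL) {
  patients <- as.data.frame(patients)
  diagnoses <- as.data.frame(diagnoses)
  prescriptions <- as.data.frame(prescriptions)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(what, " table is missing columns: ",
                           paste(miss, collapse = ", "))
  }
  need(patients, c("patient_id", "sex", "birth_year"), "patients")
  need(diagnoses, c("patient_id", "code", "date"), "diagnoses")
  need(prescriptions, c("patient_id", "drug_code", "date"), "prescriptions")

  if (is.null(patients$death_date)) patients$death_date <- as.Date(NA)
  if (is.null(diagnoses$confirmed)) diagnoses$confirmed <- TRUE
  if (is.null(prescriptions$days_supply)) prescriptions$days_supply <- NA_integer_

  patients$patient_id <- as.character(patients$patient_id)
  patients$sex <- as.character(patients$sex)
  patients$birth_year <- as.integer(patients$birth_year)
  patients$death_date <- as.Date(patients$death_date)
  diagnoses$patient_id <- as.character(diagnoses$patient_id)
  diagnoses$code <- as.character(diagnoses$code)
  diagnoses$date <- as.Date(diagnoses$date)
  diagnoses$confirmed <- as.logical(diagnoses$confirmed)
  prescriptions$patient_id <- as.character(prescriptions$patient_id)
  prescriptions$drug_code <- as.character(prescriptions$drug_code)
  prescriptions$date <- as.Date(prescriptions$date)
  prescriptions$days_supply <- as.integer(prescriptions$days_supply)

  rownames(patients) <- rownames(diagnoses) <- rownames(prescriptions) <- NULL
  structure(list(patients = patients,
                 diagnoses = diagnoses,
                 prescriptions = prescriptions,
                 study_window = as.Date(study_window),
                 parse_errors = parse_errors %||% empty_parse_errors()),
            class = "claims_bundle")
}

empty_parse_errors <- function() {
  data.frame(file = character(0), row = integer(0), message = character(0),
             stringsAsFactors = FALSE)
}

#' Read a claims bundle from three CSV files
#'
#' Files are UTF-8 CSVs with a header row and ISO-8601 (`YYYY-MM-DD`) dates.
#' A missing file or a missing mandatory column is a fatal error.  Rows whose
#' dates cannot be parsed are removed from the tables but collected in
#' `bundle$parse_errors` with their file and row number, so nothing is
#' silently dropped.
#'
#' @param patients_file,diagnoses_file,prescriptions_file CSV paths.
#' @param study_window length-2 Date (or ISO string) vector.
#' @return a `claims_bundle`.
#' @export
read_claims_bundle <- function(patients_file, diagnoses_file,
                               prescriptions_file,
                               study_window = c("2016-01-01", "2021-08-31")) {
  for (f in c(patients_file, diagnoses_file, prescriptions_file)) {
    if (!file.exists(f)) stop("claims file not found: ", f)
  }
  errors <- empty_parse_errors()
  note <- function(file, rows) {
    if (length(rows)) {
      errors <<- rbind(errors, data.frame(
        file = basename(file), row = rows,
        message = "unparseable date; row rejected", stringsAsFactors = FALSE))
    }
  }

  pat <- read.csv(patients_file, stringsAsFactors = FALSE,
                  colClasses = "character")
  dx <- read.csv(diagnoses_file, stringsAsFactors = FALSE,
                 colClasses = "character")
  rx <- read.csv(prescriptions_file, stringsAsFactors = FALSE,
                 colClasses = "character")

  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(basename(file), " is missing mandatory columns: ",
                           paste(miss, collapse = ", "))
  }
  need(pat, c("patient_id", "sex", "birth_year"), patients_file)
  need(dx, c("patient_id", "code", "date"), diagnoses_file)
  need(rx, c("patient_id", "drug_code", "date"), prescriptions_file)

  # patients: death_date may be blank
  if (is.null(pat$death_date)) pat$death_date <- ""
  dd <- as_date_safe(pat$death_date)
  bad <- !is.na(pat$death_date) & trimws(pat$death_date) != "" & is.na(dd)
  note(patients_file, which(bad))
  pat <- pat[!bad, , drop = FALSE]
  pat$death_date <- dd[!bad]
  pat$birth_year <- suppressWarnings(as.integer(pat$birth_year))

  d <- as_date_safe(dx$date)
  bad <- is.na(d)
  note(diagnoses_file, which(bad))
  dx <- dx[!bad, , drop = FALSE]; dx$date <- d[!bad]
  if (!is.null(dx$confirmed)) {
    dx$confirmed <- toupper(trimws(dx$confirmed)) %in% c("TRUE", "T", "1", "YES")
  }

  d <- as_date_safe(rx$date)
  bad <- is.na(d)
  note(prescriptions_file, which(bad))
  rx <- rx[!bad, , drop = FALSE]; rx$date <- d[!bad]
  if (!is.null(rx$days_supply)) {
    rx$days_supply <- suppressWarnings(as.integer(rx$days_supply))
  }

  claims_bundle(pat, dx, rx, study_window, parse_errors = errors)
}

#' Write a claims bundle to three CSV files
#'
#' Writes `patients.csv`, `diagnoses.csv` and `prescriptions.csv` under
#' `dir` in the schema read by [read_claims_bundle()]; a valid bundle
#' round-trips field for field.
#'
#' @param bundle a `claims_bundle`.
#' @param dir output directory (created if absent).
#' @return named character vector of the three paths, invisibly.
#' @export
write_claims_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "claims_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(patients = file.path(dir, "patients.csv"),
             diagnoses = file.path(dir, "diagnoses.csv"),
             prescriptions = file.path(dir, "prescriptions.csv"))
  pat <- bundle$patients
  pat$death_date <- ifelse(is.na(pat$death_date),
                           "", format(pat$death_date, "%Y-%m-%d"))
  write.csv(pat, paths[["patients"]], row.names = FALSE, quote = TRUE, na = "")
  dx <- bundle$diagnoses
  dx$date <- format(dx$date, "%Y-%m-%d")
  write.csv(dx, paths[["diagnoses"]], row.names = FALSE, quote = TRUE, na = "")
  rx <- bundle$prescriptions
  rx$date <- format(rx$date, "%Y-%m-%d")
  write.csv(rx, paths[["prescriptions"]], row.names = FALSE, quote = TRUE,
            na = "")
  invisible(paths)
}

#' Validate a claims bundle
#'
#' Enumerates every invariant violation as a located message; never throws
#' for data-content problems and never modifies the bundle.  Errors:
#' duplicate patient ids, diagnosis/prescription rows referencing unknown
#' patients, empty diagnosis codes, non-positive days-supply, death dates
#' before the study window start, records dated after a patient's death,
#' and record dates outside the study window beyond the configured slack.
#' Rows rejected at parse time are re-reported here as errors.
#'
#' @param bundle a `claims_bundle`.
#' @param config a [journey_config()] (supplies the date slack).
#' @return an object of class `validation_report` with `error_count`,
#'   `warning_count` and a `messages` data.frame
#'   (`severity`, `locator`, `text`).
#' @export
validate_bundle <- function(bundle, config = journey_config()) {
  stopifnot(inherits(bundle, "claims_bundle"))
  msgs <- list()
  add <- function(severity, locator, text) {
    msgs[[length(msgs) + 1L]] <<- data.frame(
      severity = severity, locator = locator, text = text,
      stringsAsFactors = FALSE)
  }
  pat <- bundle$patients; dx <- bundle$diagnoses; rx <- bundle$prescriptions
  win <- bundle$study_window

  if (nrow(bundle$parse_errors)) {
    for (i in seq_len(nrow(bundle$parse_errors))) {
      pe <- bundle$parse_errors[i, ]
      add("error", paste0(pe$file, ":row ", pe$row), pe$message)
    }
  }
  dup <- unique(pat$patient_id[duplicated(pat$patient_id)])
  for (id in dup) add("error", paste0("patients:", id), "duplicate patient_id")

  bad_sex <- !pat$sex %in% c("male", "female", "unknown")
  for (id in pat$patient_id[bad_sex]) {
    add("warning", paste0("patients:", id),
        "sex not one of male/female/unknown")
  }
  early_death <- !is.na(pat$death_date) & pat$death_date < win[1]
  for (id in pat$patient_id[early_death]) {
    add("error", paste0("patients:", id),
        "death_date precedes study window start")
  }

  known <- pat$patient_id
  for (i in which(!dx$patient_id %in% known)) {
    add("error", paste0("diagnoses:row ", i), "unknown patient_id")
  }
  for (i in which(!rx$patient_id %in% known)) {
    add("error", paste0("prescriptions:row ", i), "unknown patient_id")
  }
  for (i in which(is.na(dx$code) | trimws(dx$code) == "")) {
    add("error", paste0("diagnoses:row ", i), "empty diagnosis code")
  }
  for (i in which(!is.na(rx$days_supply) & rx$days_supply <= 0L)) {
    add("error", paste0("prescriptions:row ", i),
        "days_supply must be positive")
  }

  # records dated after the patient's death
  death <- setNames(pat$death_date, pat$patient_id)
  dxd <- death[dx$patient_id]
  for (i in which(!is.na(dxd) & dx$date > dxd)) {
    add("error", paste0("diagnoses:row ", i), "record dated after death")
  }
  rxd <- death[rx$patient_id]
  for (i in which(!is.na(rxd) & rx$date > rxd)) {
    add("error", paste0("prescriptions:row ", i), "record dated after death")
  }

  slack <- config$date_slack_days
  lo <- win[1] - slack; hi <- win[2] + slack
  for (i in which(dx$date < lo | dx$date > hi)) {
    add("error", paste0("diagnoses:row ", i),
        "date outside study window beyond slack")
  }
  for (i in which(rx$date < lo | rx$date > hi)) {
    add("error", paste0("prescriptions:row ", i),
        "date outside study window beyond slack")
  }

  messages <- if (length(msgs)) do.call(rbind, msgs) else
    data.frame(severity = character(0), locator = character(0),
               text = character(0), stringsAsFactors = FALSE)
  structure(list(error_count = sum(messages$severity == "error"),
                 warning_count = sum(messages$severity == "warning"),
                 messages = messages),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report:", x$error_count, "error(s),",
      x$warning_count, "warning(s)\n")
  if (nrow(x$messages)) print(head(x$messages, 20), row.names = FALSE)
  invisible(x)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("claims_bundle:", nrow(x$patients), "patients,",
      nrow(x$diagnoses), "diagnoses,",
      nrow(x$prescriptions), "prescriptions\n")
  cat("study window:", format(x$study_window[1]), "to",
      format(x$study_window[2]), "\n")
  if (nrow(x$parse_errors)) {
    cat(nrow(x$parse_errors), "row(s) rejected at parse time\n")
  }
  invisible(x)
}
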