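# Category labels.  category2 values double as regimen labels in reports.
CAT1_LEVELS <- c("Biologics", "Systemic oral medications",
                 "Apheresis/plasma exchange", "Topical therapy",
                 "Arthritis treatment")

# priority 1 = most dominant in combination labelling
CAT2_PRIORITY <- c(
  "IL-17 inhibitors"          = 1L,
  "TNF-alpha inhibitors"      = 2L,
  "IL-23 inhibitors"          = 3L,
  "Etretinate"                = 4L,
  "Cyclosporin"               = 5L,
  "Apheresis/plasma exchange" = 6L,
  "Corticosteroids"           = 7L,
  "Apremilast"                = 8L,
  "Methotrexate"              = 9L,
  "Topical therapy"           = 10L,
  "Other oral medications"    = 11L,
  "Arthritis treatment"       = 12L
)

SUPPLEMENTARY_CATS <- c("Topical therapy", "Other oral medications",
                        "Arthritis treatment")

#' Default drug catalog
#'
#' The built-in treatment catalog for GPP claims analyses: every drug is
#' assigned a broad category (`category1`), a regimen category (`category2`),
#' the 1-12 prioritization rank used to pick the general regimen label of a
#' combination, a main/supplementary flag (topicals, other oral medications
#' and arthritis treatments are supplementary), a discontinuation-gap class
#' (`biologic` for biologics, else `oral`/`other`), and a default coverage
#' duration in days used when a prescription row carries no days-supply
#' (28 days for most biologics, 56 for q8w dosing, 84 for q12w dosing such
#' as ustekinumab, 30 for oral and topical drugs, 1 for apheresis sessions).
#'
#' @return a `drug_catalog` object.
#' @seealso [load_catalog()], [classify_drug()]
#' @export
default_catalog <- function() {
  e <- function(code, name, cat1, cat2, cover) {
    data.frame(drug_code = code, drug_name = name, category1 = cat1,
               category2 = cat2, default_coverage_days = as.integer(cover),
               stringsAsFactors = FALSE)
  }
  bio <- "Biologics"; oral <- "Systemic oral medications"
  entries <- rbind(
    e("secukinumab",             "Secukinumab",              bio, "IL-17 inhibitors", 28),
    e("ixekizumab",              "Ixekizumab",               bio, "IL-17 inhibitors", 28),
    e("brodalumab",              "Brodalumab",               bio, "IL-17 inhibitors", 28),
    e("adalimumab",              "Adalimumab",               bio, "TNF-alpha inhibitors", 28),
    e("infliximab",              "Infliximab",               bio, "TNF-alpha inhibitors", 56),
    e("certolizumab_pegol",      "Certolizumab pegol",       bio, "TNF-alpha inhibitors", 28),
    e("guselkumab",              "Guselkumab",               bio, "IL-23 inhibitors", 56),
    e("risankizumab",            "Risankizumab",             bio, "IL-23 inhibitors", 84),
    e("ustekinumab",             "Ustekinumab",              bio, "IL-23 inhibitors", 84),
    e("etretinate",              "Etretinate",               oral, "Etretinate", 30),
    e("cyclosporin",             "Cyclosporin",              oral, "Cyclosporin", 30),
    e("systemic_corticosteroid", "Systemic corticosteroid",  oral, "Corticosteroids", 30),
    e("apremilast",              "Apremilast",               oral, "Apremilast", 30),
    e("methotrexate",            "Methotrexate",             oral, "Methotrexate", 30),
    e("antihistamine",           "Antihistamine",            oral, "Other oral medications", 30),
    e("immunosuppressant",       "Immunosuppressant",        oral, "Other oral medications", 30),
    e("apheresis",               "Apheresis/plasma exchange",
      "Apheresis/plasma exchange", "Apheresis/plasma exchange", 1),
    e("topical_corticosteroid",  "Topical corticosteroid",
      "Topical therapy", "Topical therapy", 30),
    e("topical_vitamin_d3",      "Topical vitamin D3",
      "Topical therapy", "Topical therapy", 30),
    e("topical_agent",           "Topical agent (other)",
      "Topical therapy", "Topical therapy", 30),
    e("arthritis_treatment",     "Arthritis treatment",
      "Arthritis treatment", "Arthritis treatment", 30),
    e("nsaid",                   "NSAID",
      "Arthritis treatment", "Arthritis treatment", 30)
  )
  build_catalog(entries)
}

# derive priority / supplementary / gap_class columns and validate
build_catalog <- function(entries) {
  req <- c("drug_code", "drug_name", "category1", "category2",
           "default_coverage_days")
  missing <- setdiff(req, names(entries))
  if (length(missing)) stop("catalog is missing columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(entries$drug_code)) {
    stop("duplicate drug_code in catalog: ",
         paste(unique(entries$drug_code[duplicated(entries$drug_code)]),
               collapse = ", "))
  }
  bad1 <- setdiff(unique(entries$category1), CAT1_LEVELS)
  if (length(bad1)) stop("unknown category1: ", paste(bad1, collapse = ", "))

  if (is.null(entries$priority)) {
    entries$priority <- unname(CAT2_PRIORITY[entries$category2])
  }
  if (anyNA(entries$priority)) {
    stop("unknown category2: ",
         paste(unique(entries$category2[is.na(entries$priority)]),
               collapse = ", "))
  }
  entries$priority <- as.integer(entries$priority)
  entries$is_supplementary <- entries$category2 %in% SUPPLEMENTARY_CATS
  entries$gap_class <- ifelse(entries$category1 == "Biologics", "biologic",
                       ifelse(entries$category1 == "Systemic oral medications",
                              "oral", "other"))
  entries$default_coverage_days <- as.integer(entries$default_coverage_days)
  if (any(entries$default_coverage_days <= 0)) {
    stop("default_coverage_days must be positive")
  }

  # priority must be a bijection category2 -> {1..12} over the categories used
  tab <- unique(entries[, c("category2", "priority")])
  if (anyDuplicated(tab$category2)) {
    stop("category2 mapped to more than one priority")
  }
  if (anyDuplicated(tab$priority)) {
    stop("priority assigned to more than one category2 (must be a bijection)")
  }
  if (any(tab$priority < 1L | tab$priority > 12L)) {
    stop("priorities must lie in 1..12")
  }
  expected <- unname(CAT2_PRIORITY[tab$category2])
  if (any(tab$priority != expected)) {
    stop("priority disagrees with the category prioritization table for: ",
         paste(tab$category2[tab$priority != expected], collapse = ", "))
  }

  rownames(entries) <- NULL
  structure(list(entries = entries,
                 priority_table = CAT2_PRIORITY),
            class = "drug_catalog")
}

#' Load a drug catalog
#'
#' With `path = NULL` returns the built-in [default_catalog()].  Otherwise
#' reads a CSV with columns `drug_code,drug_name,category1,category2,`
#' `default_coverage_days` and optional `priority` (validated against the
#' category prioritization table; the mapping of categories to priorities
#' must be one-to-one).
#'
#' @param path catalog CSV path, or `NULL` for the default.
#' @return a `drug_catalog` object.
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) return(default_catalog())
  if (!file.exists(path)) stop("catalog file not found: ", path)
  entries <- read.csv(path, stringsAsFactors = FALSE)
  entries$is_supplementary <- NULL  # derived, never trusted from file
  entries$gap_class <- NULL
  build_catalog(entries)
}

#' Write a catalog to CSV
#'
#' Round-trips through [load_catalog()] unchanged.
#'
#' @param catalog a `drug_catalog`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "drug_catalog"))
  write.csv(catalog$entries, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Classify a drug code
#'
#' Looks up a drug in the catalog.  Unknown codes fall back to the
#' supplementary "Other oral medications" class with a warning, so the
#' classifier is total; with `strict = TRUE` unknown codes are an error.
#'
#' @param catalog a `drug_catalog`.
#' @param drug_code single drug code string.
#' @param strict error on unknown codes instead of falling back.
#' @return a one-row data.frame (one catalog entry).
#' @export
classify_drug <- function(catalog, drug_code, strict = FALSE) {
  stopifnot(inherits(catalog, "drug_catalog"), length(drug_code) == 1L)
  i <- match(drug_code, catalog$entries$drug_code)
  if (is.na(i)) {
    if (strict) stop("unknown drug code: ", drug_code)
    warning("unknown drug code '", drug_code,
            "': falling back to Other oral medications (supplementary)")
    fb <- data.frame(drug_code = drug_code, drug_name = drug_code,
                     category1 = "Systemic oral medications",
                     category2 = "Other oral medications",
                     default_coverage_days = 30L,
                     priority = unname(CAT2_PRIORITY[["Other oral medications"]]),
                     is_supplementary = TRUE, gap_class = "oral",
                     stringsAsFactors = FALSE)
    return(fb)
  }
  catalog$entries[i, , drop = FALSE]
}

#' Discontinuation gap threshold for a drug
#'
#' A treatment is considered discontinued when coverage lapses for more than
#' 3 months (biologics) or 2 months (oral and other drugs); with the default
#' 30.4375-day month these round to 91 and 61 days.  Per-drug overrides in
#' `config$gap_overrides` win.
#'
#' @param drug_class a catalog entry row (from [classify_drug()]).
#' @param config a [journey_config()].
#' @return integer days.
#' @export
gap_threshold_days <- function(drug_class, config = journey_config()) {
  code <- drug_class$drug_code
  ov <- config$gap_overrides
  if (!is.null(ov) && code %in% names(ov)) return(as.integer(ov[[code]]))
  cls <- drug_class$gap_class
  months <- config$gap_months[[cls]]
  if (is.null(months)) stop("no gap defined for class: ", cls)
  as.integer(round(months * config$month_length_days))
}

# vectorized internal lookup: per-drug threshold for a character vector
gap_days_for_codes <- function(codes, catalog, config) {
  vapply(codes, function(cd) {
    gap_threshold_days(classify_drug(catalog, cd), config)
  }, integer(1))
}

#' @export
print.drug_catalog <- function(x, ...) {
  cat("drug_catalog with", nrow(x$entries), "drugs in",
      length(unique(x$entries$category2)), "categories\n")
  cat("supplementary categories:",
      paste(SUPPLEMENTARY_CATS, collapse = ", "), "\n")
  print(x$entries[, c("drug_code", "category2", "priority",
                      "is_supplementary", "gap_class")], row.names = FALSE)
  invisible(x)
}
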