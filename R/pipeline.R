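#' Run the full patient-journey pipeline
#'
#' Convenience driver: cohort selection, episode construction, line-of-
#' therapy derivation, TTNT and drug-survival summaries, Sankey flow
#' counts, combination frequencies and the biologic switching matrix.
#'
#' @param bundle a `claims_bundle`.
#' @param catalog a `drug_catalog`.
#' @param config a [journey_config()].
#' @return a list of data.frames: `cohort, episodes, lots, ttnt_by_line,`
#'   `ttnt_all, ttnt_by_regimen, drug_survival, sankey, combinations,`
#'   `bioswitch`.
#' @export
run_patient_journey <- function(bundle, catalog = default_catalog(),
                                config = journey_config()) {
  cohort <- build_cohort(bundle, config)
  episodes <- build_episodes(bundle, catalog, config)
  lots <- derive_lots_cohort(episodes, cohort, catalog, config)
  have_lots <- nrow(lots) > 0
  inc_ep <- episodes[episodes$patient_id %in%
                       cohort$patient_id[cohort$included], , drop = FALSE]
  list(
    cohort = cohort,
    episodes = episodes,
    lots = lots,
    ttnt_by_line = if (have_lots) ttnt_table(lots, cohort, "by_line", config),
    ttnt_all = if (have_lots) ttnt_table(lots, cohort, "all_lines", config),
    ttnt_by_regimen = if (have_lots)
      ttnt_table(lots, cohort, "by_specific_regimen", config),
    drug_survival = if (nrow(inc_ep))
      drug_survival_table(episodes, cohort, catalog, config),
    sankey = if (have_lots) sankey_flows(lots, cohort),
    combinations = if (nrow(inc_ep))
      combination_frequencies(episodes, cohort, catalog = catalog),
    bioswitch = bioswitch_matrix(episodes, cohort, catalog)
  )
}

#' Write pipeline reports to CSV
#'
#' Writes each non-empty result table of [run_patient_journey()] as a CSV
#' under `dir`.  Tables are already deterministically ordered, so repeated
#' runs on the same inputs produce byte-identical files.
#'
#' @param results list from [run_patient_journey()].
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
write_journey_reports <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  for (nm in names(results)) {
    tab <- results[[nm]]
    if (is.null(tab) || !is.data.frame(tab)) next
    tab <- as.data.frame(lapply(tab, function(col) {
      if (inherits(col, "Date")) format(col, "%Y-%m-%d") else col
    }), stringsAsFactors = FALSE, check.names = FALSE)
    path <- file.path(dir, paste0(nm, ".csv"))
    write.csv(tab, path, row.names = FALSE, quote = TRUE, na = "")
    written <- c(written, path)
  }
  invisible(written)
}
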