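NO_FURTHER <- "No further therapy"

filter_stratum <- function(cohort, stratum) {
  inc <- cohort[cohort$included, , drop = FALSE]
  switch(stratum,
         all = inc,
         psv = inc[inc$has_psv, , drop = FALSE],
         no_psv = inc[!inc$has_psv, , drop = FALSE],
         age65 = inc[inc$age_ge65, , drop = FALSE],
         age75 = inc[inc$age_ge75, , drop = FALSE],
         stop("unknown stratum: ", stratum))
}

#' Sankey flow counts over the first lines of therapy
#'
#' Counts patients flowing from the general regimen at line `k` to the
#' general regimen at line `k + 1`, for `k = 1 .. depth - 1`, with an
#' explicit "No further therapy" sink for patients lacking line `k + 1`.
#' Outflows from every regimen at line `k` therefore sum exactly to that
#' regimen's patient count at line `k` (conservation).
#'
#' @param lots line-of-therapy table.
#' @param cohort cohort table (for stratification).
#' @param depth number of lines covered (default 3; must be >= 2).
#' @param stratum one of `"all"`, `"psv"`, `"no_psv"`, `"age65"`, `"age75"`.
#' @return data.frame `line, from, to, n`.
#' @export
sankey_flows <- function(lots, cohort, depth = 3L, stratum = "all") {
  if (depth < 2) stop("sankey_flows(): depth must be >= 2")
  keep <- filter_stratum(cohort, stratum)$patient_id
  lt <- lots[lots$patient_id %in% keep & lots$lot_number <= depth, ,
             drop = FALSE]
  if (nrow(lt) == 0) {
    return(data.frame(line = integer(0), from = character(0),
                      to = character(0), n = integer(0)))
  }
  rows <- list()
  for (k in seq_len(depth - 1L)) {
    at_k <- lt[lt$lot_number == k, c("patient_id", "general_regimen")]
    if (nrow(at_k) == 0) next
    at_k1 <- lt[lt$lot_number == k + 1L, c("patient_id", "general_regimen")]
    to <- at_k1$general_regimen[match(at_k$patient_id, at_k1$patient_id)]
    to[is.na(to)] <- NO_FURTHER
    counts <- table(from = at_k$general_regimen, to = to)
    df <- as.data.frame(counts, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, , drop = FALSE]
    if (nrow(df)) {
      rows[[k]] <- data.frame(line = k, from = df$from, to = df$to,
                              n = as.integer(df$Freq),
                              stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(line = integer(0), from = character(0), to = character(0),
               n = integer(0))
  out <- out[order(out$line, out$from, out$to, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Combination frequencies
#'
#' For each anchor treatment category, the percentage of anchor-exposed
#' patients with at least one episode of a partner category overlapping an
#' anchor episode by at least one day (half-open intervals, so touching
#' episodes do not overlap).
#'
#' @param episodes episode table.
#' @param cohort cohort table.
#' @param anchors character vector of anchor `category2` labels; default is
#'   every non-supplementary category present in the episode table.
#' @param catalog a `drug_catalog`.
#' @return data.frame `anchor, partner, n_exposed, n_with_partner, pct`.
#' @export
combination_frequencies <- function(episodes, cohort, anchors = NULL,
                                    catalog = default_catalog()) {
  inc <- cohort$patient_id[cohort$included]
  ep <- episodes[episodes$patient_id %in% inc, , drop = FALSE]
  present <- unique(ep$category2)
  if (is.null(anchors)) {
    anchors <- sort_c(setdiff(present, SUPPLEMENTARY_CATS))
  }
  unknown <- setdiff(anchors, names(catalog$priority_table))
  if (length(unknown)) stop("unknown anchor categories: ",
                            paste(unknown, collapse = ", "))
  partners <- sort_c(present)
  rows <- list()
  for (a in anchors) {
    aep <- ep[ep$category2 == a, , drop = FALSE]
    exposed <- unique(aep$patient_id)
    for (p in setdiff(partners, a)) {
      pep <- ep[ep$category2 == p & ep$patient_id %in% exposed, ,
                drop = FALSE]
      hit <- vapply(exposed, function(id) {
        ai <- aep[aep$patient_id == id, , drop = FALSE]
        pi <- pep[pep$patient_id == id, , drop = FALSE]
        if (nrow(pi) == 0) return(FALSE)
        any(outer(as.integer(ai$start), as.integer(pi$end), `<`) &
              outer(as.integer(ai$end), as.integer(pi$start), `>`))
      }, logical(1))
      rows[[length(rows) + 1L]] <- data.frame(
        anchor = a, partner = p, n_exposed = length(exposed),
        n_with_partner = sum(hit),
        pct = if (length(exposed)) 100 * sum(hit) / length(exposed) else 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Biologic switching matrix
#'
#' For each biologic drug, takes each recipient's last treatment episode of
#' that drug; the patient is a switcher when a different biologic has an
#' episode starting after that last episode ends and before the patient's
#' end of follow-up, and the switch destination is the earliest such start
#' (ties broken by catalog priority, then drug code).  Restarting the same
#' biologic is never a switch.
#'
#' @param episodes episode table.
#' @param cohort cohort table (follow-up ends and stratification).
#' @param catalog a `drug_catalog`.
#' @param stratum see [sankey_flows()].
#' @param max_window_days optional cap on the days between the last episode
#'   end and the destination start (default unbounded within follow-up).
#' @return data.frame with one row per (index biologic, destination class):
#'   `biologic, n_treated, n_switched, dest_class, n_dest`; non-switching
#'   drugs appear with `dest_class = NA` and `n_dest = 0`.
#' @export
bioswitch_matrix <- function(episodes, cohort, catalog = default_catalog(),
                             stratum = "all", max_window_days = Inf) {
  keep <- filter_stratum(cohort, stratum)
  ep <- episodes[episodes$patient_id %in% keep$patient_id, , drop = FALSE]
  entries <- catalog$entries
  bio_codes <- entries$drug_code[entries$category1 == "Biologics"]
  bep <- ep[ep$drug_code %in% bio_codes, , drop = FALSE]
  if (nrow(bep) == 0) {
    return(data.frame(biologic = character(0), n_treated = integer(0),
                      n_switched = integer(0), dest_class = character(0),
                      n_dest = integer(0)))
  }
  fend <- setNames(keep$followup_end, keep$patient_id)
  prio <- setNames(entries$priority, entries$drug_code)

  rows <- list()
  for (drug in sort_c(unique(bep$drug_code))) {
    dep <- bep[bep$drug_code == drug, , drop = FALSE]
    recipients <- unique(dep$patient_id)
    dests <- character(0)
    n_switched <- 0L
    for (id in recipients) {
      last_end <- max(dep$end[dep$patient_id == id])
      cand <- bep[bep$patient_id == id & bep$drug_code != drug &
                    bep$start > last_end & bep$start < fend[[id]], ,
                  drop = FALSE]
      if (is.finite(max_window_days)) {
        cand <- cand[days_between(last_end, cand$start) <= max_window_days, ,
                     drop = FALSE]
      }
      if (nrow(cand) == 0) next
      cand <- cand[order(as.integer(cand$start),
                         prio[cand$drug_code], cand$drug_code), ,
                   drop = FALSE]
      dest_drug <- cand$drug_code[1]
      dests <- c(dests,
                 entries$category2[match(dest_drug, entries$drug_code)])
      n_switched <- n_switched + 1L
    }
    if (n_switched == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        biologic = drug, n_treated = length(recipients), n_switched = 0L,
        dest_class = NA_character_, n_dest = 0L, stringsAsFactors = FALSE)
    } else {
      tab <- table(dests)
      rows[[length(rows) + 1L]] <- data.frame(
        biologic = drug, n_treated = length(recipients),
        n_switched = n_switched, dest_class = names(tab),
        n_dest = as.integer(tab), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
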