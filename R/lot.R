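# --- internal interval helpers (integer day grids, half-open) --------------

# merge a set of [s, e) intervals, bridging gaps <= gap
merge_intervals_int <- function(s, e, gap = 0L) {
  if (length(s) == 0) return(cbind(s = integer(0), e = integer(0)))
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  out_s <- s[1]; out_e <- e[1]; res <- list()
  for (i in seq_along(s)[-1]) {
    if (s[i] - out_e <= gap) {
      out_e <- max(out_e, e[i])
    } else {
      res[[length(res) + 1L]] <- c(out_s, out_e)
      out_s <- s[i]; out_e <- e[i]
    }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e)
  m <- do.call(rbind, res)
  colnames(m) <- c("s", "e")
  m
}

#' Regimen timeline of one patient
#'
#' Partitions the patient's follow-up `[index_date, followup_end)` at every
#' episode boundary into maximal states of constant drug composition.  Drug
#' episodes are first lifted to the treatment-category level (episodes of
#' different drugs in one category pool, and within-category lapses up to
#' the category's discontinuation gap are bridged), then a sweep line over
#' the boundaries emits one state per segment listing the concurrently
#' active main and supplementary categories.  Periods with no active drug
#' are emitted as explicit untreated states, so the states tile the whole
#' follow-up.
#'
#' @param episodes episode rows of one patient (from [build_episodes()]).
#' @param index_date,followup_end the patient's follow-up bounds.
#' @param catalog a `drug_catalog`.
#' @param config a [journey_config()].
#' @param warn_trimmed warn when episodes extend outside the follow-up
#'   window (they are trimmed to it).
#' @return a data.frame of states: `start, end` (Dates), `mains`, `supps`
#'   (sorted category labels joined by `"|"`, empty string when none).
#' @export
build_regimen_timeline <- function(episodes, index_date, followup_end,
                                   catalog = default_catalog(),
                                   config = journey_config(),
                                   warn_trimmed = FALSE) {
  index_i <- as.integer(as.Date(index_date))
  fend_i <- as.integer(as.Date(followup_end))
  stopifnot(fend_i > index_i)
  empty_state <- function() {
    data.frame(start = as.Date(index_i, origin = "1970-01-01"),
               end = as.Date(fend_i, origin = "1970-01-01"),
               mains = "", supps = "", stringsAsFactors = FALSE)
  }
  if (nrow(episodes) == 0) return(empty_state())

  s <- pmax(as.integer(episodes$start), index_i)
  e <- pmin(as.integer(episodes$end), fend_i)
  keep <- e > s
  if (warn_trimmed &&
      (any(!keep) || any(as.integer(episodes$start) < index_i) ||
       any(as.integer(episodes$end) > fend_i))) {
    warning("episodes outside [index_date, followup_end) were trimmed")
  }
  if (!any(keep)) return(empty_state())
  ep <- data.frame(drug_code = episodes$drug_code[keep],
                   s = s[keep], e = e[keep], stringsAsFactors = FALSE)

  # category-level intervals, bridged with the category's gap threshold
  cls <- lapply(unique(ep$drug_code), function(cd) {
    classify_drug(catalog, cd, strict = config$strict_drug_codes)
  })
  cls <- do.call(rbind, cls)
  ep$category2 <- cls$category2[match(ep$drug_code, cls$drug_code)]
  cat_tab <- unique(cls[, c("category2", "is_supplementary")])
  cat_gap <- vapply(split(cls, cls$category2), function(g) {
    max(vapply(seq_len(nrow(g)), function(i) {
      gap_threshold_days(g[i, ], config)
    }, integer(1)))
  }, integer(1))

  cat_iv <- lapply(split(ep, ep$category2), function(g) {
    merge_intervals_int(g$s, g$e, gap = cat_gap[[g$category2[1]]])
  })

  bounds <- sort(unique(c(index_i, fend_i,
                          unlist(lapply(cat_iv, function(m) c(m[, "s"], m[, "e"]))))))
  bounds <- bounds[bounds >= index_i & bounds <= fend_i]
  st <- bounds[-length(bounds)]
  en <- bounds[-1]

  cat_names <- names(cat_iv)
  cat_supp <- cat_tab$is_supplementary[match(cat_names, cat_tab$category2)]
  # active[k, j]: category j covers state k (intervals align with bounds)
  act <- vapply(cat_iv, function(m) {
    vapply(seq_along(st), function(k) {
      any(m[, "s"] <= st[k] & m[, "e"] >= en[k])
    }, logical(1))
  }, logical(length(st)))
  act <- matrix(act, nrow = length(st))
  mains <- vapply(seq_along(st), function(k) {
    paste(sort_c(cat_names[act[k, ] & !cat_supp]), collapse = "|")
  }, character(1))
  supps <- vapply(seq_along(st), function(k) {
    paste(sort_c(cat_names[act[k, ] & cat_supp]), collapse = "|")
  }, character(1))
  out <- data.frame(start = st, end = en, mains = mains, supps = supps,
                    stringsAsFactors = FALSE)

  # merge consecutive states with identical composition
  comp <- paste(out$mains, out$supps, sep = "\r")
  grp <- cumsum(c(TRUE, comp[-1] != comp[-length(comp)]))
  out <- data.frame(
    start = as.Date(tapply(out$start, grp, min), origin = "1970-01-01"),
    end = as.Date(tapply(out$end, grp, max), origin = "1970-01-01"),
    mains = tapply(out$mains, grp, `[`, 1),
    supps = tapply(out$supps, grp, `[`, 1),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Label a regimen
#'
#' The general regimen of a line is its member category with the smallest
#' prioritization rank (for supplementary-only lines, the highest-priority
#' supplementary category).  The specific regimen is the alphabetically
#' sorted main categories joined by `" + "`, with a `" + supplementary
#' drug"` suffix whenever any supplementary category co-occurs.
#'
#' @param main_categories character vector of category labels forming the
#'   line (for supplementary-only lines, the supplementary categories).
#' @param supplementary_present does any (additional) supplementary category
#'   co-occur with the line?
#' @param catalog a `drug_catalog` (supplies the priority table).
#' @param config a [journey_config()]; with `apheresis_dominates = TRUE`,
#'   apheresis/plasma exchange labels any combination containing it.
#' @return list with `general_regimen` and `specific_regimen`.
#' @export
label_regimen <- function(main_categories, supplementary_present = FALSE,
                          catalog = default_catalog(),
                          config = journey_config()) {
  cats <- unique(main_categories)
  if (length(cats) == 0) stop("label_regimen(): empty category set")
  pr <- catalog$priority_table[cats]
  if (anyNA(pr)) stop("unknown categories: ",
                      paste(cats[is.na(pr)], collapse = ", "))
  general <- names(pr)[which.min(pr)]
  if (config$apheresis_dominates && "Apheresis/plasma exchange" %in% cats) {
    general <- "Apheresis/plasma exchange"
  }
  all_supp <- all(cats %in% SUPPLEMENTARY_CATS)
  if (all_supp) {
    specific <- general
    if (length(cats) > 1L || supplementary_present) {
      specific <- paste0(specific, " + supplementary drug")
    }
  } else {
    specific <- paste(sort_c(cats), collapse = " + ")
    if (supplementary_present) {
      specific <- paste0(specific, " + supplementary drug")
    }
  }
  list(general_regimen = general, specific_regimen = specific)
}

#' Derive lines of therapy from a regimen timeline
#'
#' Walks the timeline applying the line-of-therapy transition rules:
#' (1) a main category starting within the combination window of the
#' current line's start joins it as a combination; (2) a later main start
#' is an add-on and opens a new line comprising all then-active main
#' categories; (3) after all main drugs end, the next main start opens a
#' new line regardless of similarity (same-category resumes within the
#' discontinuation gap were already bridged at episode/category level, so
#' they never reach this rule); (4) discontinuing one component of a
#' combination opens a new line of the remaining main categories;
#' (5) supplementary starts/stops never change the line while a main drug
#' is active; (6) periods with only supplementary drugs form their own
#' line; (7) an identical regimen resuming within its components' gap
#' thresholds continues the same line (via the category-level bridging).
#'
#' @param timeline data.frame from [build_regimen_timeline()].
#' @param catalog a `drug_catalog`.
#' @param config a [journey_config()].
#' @return a data.frame with one row per line: `lot_number, start, end,`
#'   `specific_regimen, general_regimen, is_last` (end is the line's last
#'   covered day, exclusive).
#' @export
derive_lots <- function(timeline, catalog = default_catalog(),
                        config = journey_config()) {
  win <- config$combination_window_days
  split_cats <- function(x) if (x == "") character(0) else strsplit(x, "|", fixed = TRUE)[[1]]

  lots <- list()
  push <- function(founding, start, end) {
    lots[[length(lots) + 1L]] <<- list(F = founding, start = start, end = end,
                                       supp_only = FALSE)
  }
  cur <- NULL
  prev_main <- character(0)

  for (k in seq_len(nrow(timeline))) {
    M <- split_cats(timeline$mains[k])
    st <- timeline$start[k]; en <- timeline$end[k]
    if (length(M) == 0) { prev_main <- M; next }

    if (is.null(cur)) {
      cur <- list(F = M, start = st, end = en)
    } else if (length(prev_main) == 0) {
      # rule (3): all mains ended before this state (unbridged lapse)
      push(cur$F, cur$start, cur$end)
      cur <- list(F = M, start = st, end = en)
    } else {
      added <- setdiff(M, prev_main)
      removed <- setdiff(prev_main, M)
      if (length(removed) == 0 && length(added) > 0) {
        if (days_between(cur$start, st) <= win) {
          cur$F <- sort_c(union(cur$F, added))   # rule (1): combination
          cur$end <- en
        } else {                                 # rule (2): add-on
          push(cur$F, cur$start, st)
          cur <- list(F = M, start = st, end = en)
        }
      } else if (length(added) == 0 && length(removed) > 0) {
        if (setequal(M, cur$F)) {
          cur$end <- en
        } else {                                 # rule (4): discontinuation
          push(cur$F, cur$start, st)
          cur <- list(F = M, start = st, end = en)
        }
      } else if (length(added) > 0 && length(removed) > 0) {
        push(cur$F, cur$start, st)               # simultaneous switch
        cur <- list(F = M, start = st, end = en)
      } else {
        cur$end <- en
      }
    }
    prev_main <- M
  }
  if (!is.null(cur)) push(cur$F, cur$start, cur$end)

  main_lots <- lots

  # rule (6): supplementary-only lines in spans not covered by a main line
  covered <- function(d) {
    any(vapply(main_lots, function(l) d >= l$start && d < l$end, logical(1)))
  }
  supp_states <- timeline[timeline$mains == "" & timeline$supps != "", ,
                          drop = FALSE]
  supp_lots <- list()
  if (nrow(supp_states) > 0) {
    free <- vapply(seq_len(nrow(supp_states)), function(i) {
      !covered(supp_states$start[i])
    }, logical(1))
    supp_states <- supp_states[free, , drop = FALSE]
    if (nrow(supp_states) > 0) {
      # contiguous supp-only states form one line
      grp <- cumsum(c(TRUE, supp_states$start[-1] !=
                              supp_states$end[-nrow(supp_states)]))
      for (g in split(supp_states, grp)) {
        span <- days_between(min(g$start), max(g$end))
        if (span < config$min_supp_lot_days) next
        cats <- unique(unlist(lapply(g$supps, split_cats)))
        supp_lots[[length(supp_lots) + 1L]] <-
          list(F = cats, start = min(g$start), end = max(g$end),
               supp_only = TRUE)
      }
    }
  }

  all_lots <- c(lapply(main_lots, function(l) { l$supp_only <- FALSE; l }),
                supp_lots)
  if (length(all_lots) == 0) {
    return(data.frame(lot_number = integer(0), start = as.Date(character(0)),
                      end = as.Date(character(0)),
                      specific_regimen = character(0),
                      general_regimen = character(0), is_last = logical(0)))
  }
  all_lots <- all_lots[order(vapply(all_lots, function(l) as.integer(l$start),
                                    integer(1)))]

  # supplementary co-occurrence for main lines (rule 5: label only)
  has_supp_overlap <- function(l) {
    any(timeline$supps != "" & timeline$start < l$end & timeline$end > l$start)
  }

  rows <- lapply(seq_along(all_lots), function(i) {
    l <- all_lots[[i]]
    lab <- label_regimen(l$F,
                         supplementary_present =
                           if (l$supp_only) FALSE else has_supp_overlap(l),
                         catalog = catalog, config = config)
    data.frame(lot_number = i, start = l$start, end = l$end,
               specific_regimen = lab$specific_regimen,
               general_regimen = lab$general_regimen,
               is_last = i == length(all_lots), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Derive lines of therapy for a whole cohort
#'
#' @param episodes episode table from [build_episodes()].
#' @param cohort cohort table from [build_cohort()]; only included patients
#'   contribute.
#' @param catalog a `drug_catalog`.
#' @param config a [journey_config()].
#' @return data.frame `patient_id, lot_number, start, end,
#'   specific_regimen, general_regimen, is_last`.
#' @export
derive_lots_cohort <- function(episodes, cohort,
                               catalog = default_catalog(),
                               config = journey_config()) {
  inc <- cohort[cohort$included, , drop = FALSE]
  ep_by <- split(episodes, episodes$patient_id)
  empty_ep <- episodes[0, ]
  pieces <- lapply(seq_len(nrow(inc)), function(i) {
    p <- inc[i, ]
    ep <- ep_by[[p$patient_id]] %||% empty_ep
    tl <- build_regimen_timeline(ep, p$index_date, p$followup_end,
                                 catalog, config)
    lots <- derive_lots(tl, catalog, config)
    if (nrow(lots) == 0) return(NULL)
    cbind(patient_id = p$patient_id, lots, stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0) {
    return(data.frame(patient_id = character(0), lot_number = integer(0),
                      start = as.Date(character(0)),
                      end = as.Date(character(0)),
                      specific_regimen = character(0),
                      general_regimen = character(0), is_last = logical(0)))
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$patient_id, out$lot_number, method = "radix"), ]
  rownames(out) <- NULL
  out
}
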