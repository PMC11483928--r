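#' Coverage intervals from prescriptions
#'
#' Each prescription of a patient-drug yields a half-open coverage interval
#' `[date, date + supply)`, where supply is the row's days-supply when
#' present and otherwise the drug's default coverage duration from the
#' catalog.  Same-day fills yield identical-start intervals; the merge step
#' resolves the overlap.
#'
#' @param prescriptions prescription rows for a single patient-drug.
#' @param catalog a `drug_catalog`.
#' @return a data.frame `patient_id, drug_code, start, end` sorted by start.
#' @export
coverage_intervals <- function(prescriptions, catalog = default_catalog()) {
  if (nrow(prescriptions) == 0) {
    return(data.frame(patient_id = character(0), drug_code = character(0),
                      start = as.Date(character(0)),
                      end = as.Date(character(0))))
  }
  code <- unique(prescriptions$drug_code)
  stopifnot(length(code) == 1L, length(unique(prescriptions$patient_id)) == 1L)
  default_cover <- classify_drug(catalog, code)$default_coverage_days
  supply <- ifelse(is.na(prescriptions$days_supply),
                   default_cover, prescriptions$days_supply)
  if (any(supply <= 0)) stop("days_supply must be positive")
  out <- data.frame(patient_id = prescriptions$patient_id,
                    drug_code = prescriptions$drug_code,
                    start = prescriptions$date,
                    end = prescriptions$date + supply)
  out[order(out$start, out$end), , drop = FALSE]
}

# core merger on sorted integer day grids; returns matrix (start, end, n)
merge_episodes_int <- function(s, e, gap_days, stockpile = FALSE) {
  n <- length(s)
  ep_start <- s[1]; ep_end <- e[1]; ep_n <- 1L
  eps <- vector("list", n)
  k <- 0L
  for (i in seq_len(n)[-1]) {
    if (s[i] - ep_end <= gap_days) {
      if (stockpile) {
        # unused overlap days are carried forward: a fill starting before
        # the current covered end pushes coverage out by its full supply
        overlap <- max(0, ep_end - s[i])
        ep_end <- max(ep_end, e[i] + overlap)
      } else {
        ep_end <- max(ep_end, e[i])
      }
      ep_n <- ep_n + 1L
    } else {
      k <- k + 1L
      eps[[k]] <- c(ep_start, ep_end, ep_n)
      ep_start <- s[i]; ep_end <- e[i]; ep_n <- 1L
    }
  }
  k <- k + 1L
  eps[[k]] <- c(ep_start, ep_end, ep_n)
  matrix(unlist(eps[seq_len(k)]), ncol = 3, byrow = TRUE)
}

#' Merge coverage intervals into treatment episodes
#'
#' Intervals of one patient-drug whose lapse (next start minus current
#' covered end) is at most `gap_days` belong to the same treatment episode;
#' a longer lapse is a discontinuation and splits episodes.  By default
#' overlapping coverage truncates (the episode never extends beyond the
#' latest covered end); with `stockpile = TRUE`, overlap days are carried
#' forward and extend the episode.
#'
#' @param intervals data.frame from [coverage_intervals()] (one
#'   patient-drug).
#' @param gap_days non-negative integer discontinuation threshold in days.
#' @param stockpile carry overlapping supply forward.
#' @return a data.frame of episodes: `patient_id, drug_code, episode_index,`
#'   `start, end, duration_days, n_prescriptions, is_last`.
#' @export
merge_into_episodes <- function(intervals, gap_days, stockpile = FALSE) {
  if (gap_days < 0) stop("gap_days must be non-negative")
  n <- nrow(intervals)
  if (n == 0) {
    return(data.frame(patient_id = character(0), drug_code = character(0),
                      episode_index = integer(0),
                      start = as.Date(character(0)),
                      end = as.Date(character(0)),
                      duration_days = integer(0),
                      n_prescriptions = integer(0), is_last = logical(0)))
  }
  o <- order(intervals$start, intervals$end)
  s <- as.integer(intervals$start[o])
  e <- as.integer(intervals$end[o])
  m <- merge_episodes_int(s, e, gap_days, stockpile)
  data.frame(
    patient_id = intervals$patient_id[1],
    drug_code = intervals$drug_code[1],
    episode_index = seq_len(nrow(m)),
    start = as.Date(m[, 1], origin = "1970-01-01"),
    end = as.Date(m[, 2], origin = "1970-01-01"),
    duration_days = as.integer(m[, 2] - m[, 1]),
    n_prescriptions = as.integer(m[, 3]),
    is_last = seq_len(nrow(m)) == nrow(m),
    stringsAsFactors = FALSE)
}

#' Build the episode table for a whole bundle
#'
#' Runs [coverage_intervals()] and [merge_into_episodes()] for every
#' patient-drug in the bundle, using each drug's class-specific gap
#' threshold (3 months for biologics, 2 months otherwise, configurable per
#' drug).
#'
#' @param bundle a `claims_bundle`.
#' @param catalog a `drug_catalog`.
#' @param config a [journey_config()].
#' @return episode data.frame with an added `category2` column, ordered by
#'   patient, drug and episode index.
#' @export
build_episodes <- function(bundle, catalog = default_catalog(),
                           config = journey_config()) {
  stopifnot(inherits(bundle, "claims_bundle"))
  rx <- bundle$prescriptions
  if (nrow(rx) == 0) {
    out <- merge_into_episodes(coverage_intervals(rx, catalog), 0L)
    out$category2 <- character(0)
    return(out)
  }
  # per-drug class lookups, computed once
  drugs <- unique(rx$drug_code)
  cls <- lapply(drugs, classify_drug, catalog = catalog,
                strict = config$strict_drug_codes)
  gap <- vapply(cls, gap_threshold_days, integer(1), config = config)
  cover <- vapply(cls, function(cl) cl$default_coverage_days, integer(1))
  cat2 <- vapply(cls, function(cl) cl$category2, character(1))
  names(gap) <- names(cover) <- names(cat2) <- drugs

  di <- match(rx$drug_code, drugs)
  supply <- ifelse(is.na(rx$days_supply), cover[di], rx$days_supply)
  if (any(supply <= 0)) stop("days_supply must be positive")
  s_all <- as.integer(rx$date)
  e_all <- s_all + as.integer(supply)

  key <- paste(rx$patient_id, rx$drug_code, sep = "\r")
  o <- order(key, s_all, e_all, method = "radix")
  idx <- split(o, key[o])

  pieces <- lapply(idx, function(ii) {
    code <- rx$drug_code[ii[1]]
    m <- merge_episodes_int(s_all[ii], e_all[ii], gap[[code]],
                            stockpile = config$stockpile)
    cbind(m, seq_len(nrow(m)))
  })
  m <- do.call(rbind, pieces)
  reps <- vapply(pieces, nrow, integer(1))
  pid <- rep(vapply(idx, function(ii) rx$patient_id[ii[1]], character(1)),
             reps)
  code <- rep(vapply(idx, function(ii) rx$drug_code[ii[1]], character(1)),
              reps)
  out <- data.frame(
    patient_id = pid, drug_code = code, episode_index = as.integer(m[, 4]),
    start = as.Date(m[, 1], origin = "1970-01-01"),
    end = as.Date(m[, 2], origin = "1970-01-01"),
    duration_days = as.integer(m[, 2] - m[, 1]),
    n_prescriptions = as.integer(m[, 3]),
    is_last = c(m[-1, 4] <= m[-nrow(m), 4], TRUE),
    category2 = unname(cat2[code]),
    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$drug_code, out$episode_index,
                   method = "radix"), ]
  rownames(out) <- NULL
  out
}
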