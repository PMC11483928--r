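#' Kaplan-Meier product-limit fit
#'
#' From-scratch product-limit estimator: at each distinct event time `t_i`
#' with `d_i` events among `n_i` at risk, `S(t) = prod(1 - d_i / n_i)` over
#' `t_i <= t`, with Greenwood's variance
#' `S(t)^2 * sum(d_i / (n_i (n_i - d_i)))`.  Units censored at an event
#' time are counted at risk at that time (the standard convention).
#'
#' @param durations positive numeric durations.
#' @param events logical; `TRUE` = event, `FALSE` = censored.
#' @return an object of class `km_curve`: `time` (distinct event times),
#'   `n_risk`, `n_event`, `surv`, `greenwood_var`, plus `n` (sample size)
#'   and `n_events` (total events).
#' @export
km_fit <- function(durations, events) {
  if (length(durations) == 0) stop("km_fit(): no samples")
  stopifnot(length(durations) == length(events))
  if (any(is.na(durations)) || any(is.na(events))) {
    stop("km_fit(): NA in durations or events")
  }
  if (any(durations <= 0)) stop("km_fit(): durations must be positive")
  events <- as.logical(events)

  times <- sort(unique(durations[events]))
  n_risk <- vapply(times, function(t) sum(durations >= t), numeric(1))
  n_event <- vapply(times, function(t) sum(durations == t & events),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  # at a time where everyone at risk fails, S hits 0 and the Greenwood term
  # is undefined; the variance there is 0 because surv^2 = 0
  term <- ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), 0)
  gw <- surv^2 * cumsum(term)
  structure(list(time = times, n_risk = n_risk, n_event = n_event,
                 surv = surv, greenwood_var = gw,
                 n = length(durations), n_events = sum(events)),
            class = "km_curve")
}

#' Survival probability at given times
#'
#' Step-function evaluation of a fitted curve; `S = 1` before the first
#' event time.
#'
#' @param curve a `km_curve`.
#' @param times numeric vector.
#' @return numeric vector of survival probabilities.
#' @export
km_surv_at <- function(curve, times) {
  vapply(times, function(t) {
    i <- findInterval(t, curve$time)
    if (i == 0) 1 else curve$surv[i]
  }, numeric(1))
}

# pointwise CI band on the log(-log S) scale; (0,0) at S == 0, (1,1) at S == 1
km_loglog_band <- function(curve, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  S <- curve$surv
  lower <- upper <- numeric(length(S))
  for (i in seq_along(S)) {
    if (S[i] <= 0) { lower[i] <- 0; upper[i] <- 0 }
    else if (S[i] >= 1) { lower[i] <- 1; upper[i] <- 1 }
    else {
      se_ll <- sqrt(curve$greenwood_var[i]) / (S[i] * abs(log(S[i])))
      lower[i] <- S[i]^exp(z * se_ll)
      upper[i] <- S[i]^exp(-z * se_ll)
    }
  }
  list(lower = lower, upper = upper)
}

#' Kaplan-Meier median and its confidence interval
#'
#' The median is the smallest event time at which `S(t) <= 0.5` (`NA` when
#' the curve never reaches 0.5).  The 95% interval inverts the pointwise
#' log-log-transformed confidence band: the bounds are the smallest event
#' times at which the band's lower (respectively upper) limit drops to 0.5
#' or below; an upper bound the data cannot determine is reported as `Inf`.
#'
#' @param curve a `km_curve`.
#' @param conf confidence level (default 0.95).
#' @return list `median`, `ci_lower`, `ci_upper` (same time units as the
#'   fitted durations).
#' @export
km_median_ci <- function(curve, conf = 0.95) {
  stopifnot(inherits(curve, "km_curve"))
  first_at <- function(v) {
    i <- which(v <= 0.5 + 1e-12)
    if (length(i)) curve$time[min(i)] else NA_real_
  }
  med <- first_at(curve$surv)
  band <- km_loglog_band(curve, conf)
  lo <- first_at(band$lower)
  hi <- first_at(band$upper)
  if (is.na(med)) return(list(median = NA_real_, ci_lower = NA_real_,
                              ci_upper = NA_real_))
  if (is.na(hi)) hi <- Inf
  if (is.na(lo)) lo <- med  # degenerate: band never below 0.5 before median
  list(median = med, ci_lower = lo, ci_upper = hi)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("km_curve:", x$n, "units,", x$n_events, "events,",
      length(x$time), "distinct event times\n")
  med <- km_median_ci(x)
  cat("median:", format(med$median), " 95% CI [", format(med$ci_lower),
      ",", format(med$ci_upper), "]\n")
  invisible(x)
}

# --- TTNT ------------------------------------------------------------------

#' Time-to-next-therapy samples
#'
#' Each non-last line of a patient contributes an event sample, the days
#' from its start to the next line's start; the last line contributes a
#' censored sample, the days from its start to the end of follow-up.
#'
#' @param lots line-of-therapy table from [derive_lots_cohort()].
#' @param cohort cohort table (supplies `followup_end`).
#' @return data.frame `patient_id, lot_number, specific_regimen,
#'   general_regimen, duration_days, event`.
#' @export
ttnt_samples <- function(lots, cohort) {
  if (nrow(lots) == 0) {
    return(data.frame(patient_id = character(0), lot_number = integer(0),
                      specific_regimen = character(0),
                      general_regimen = character(0),
                      duration_days = integer(0), event = logical(0)))
  }
  fend <- setNames(cohort$followup_end, cohort$patient_id)
  pieces <- lapply(split(lots, lots$patient_id), function(g) {
    g <- g[order(g$lot_number), , drop = FALSE]
    n <- nrow(g)
    nxt <- c(g$start[-1], as.Date(NA))
    dur <- ifelse(seq_len(n) < n,
                  days_between(g$start, nxt),
                  days_between(g$start, fend[[g$patient_id[1]]]))
    data.frame(patient_id = g$patient_id, lot_number = g$lot_number,
               specific_regimen = g$specific_regimen,
               general_regimen = g$general_regimen,
               duration_days = as.integer(dur),
               event = seq_len(n) < n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  bad <- out$duration_days <= 0
  if (any(bad)) {
    warning(sum(bad), " zero-length TTNT sample(s) dropped")
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

km_summary_row <- function(durations, events, config) {
  fit <- km_fit(durations, events)
  med <- km_median_ci(fit)
  ev <- durations[events]
  m <- function(d) months_from_days(d, config$month_length_days)
  data.frame(n = fit$n, n_events = fit$n_events,
             median_months = m(med$median),
             ci_lower_months = m(med$ci_lower),
             ci_upper_months = if (is.infinite(med$ci_upper)) Inf
                               else m(med$ci_upper),
             range_min_months = if (length(ev)) m(min(ev)) else NA_real_,
             range_max_months = if (length(ev)) m(max(ev)) else NA_real_,
             raw_median_months = m(median(durations)))
}

#' Time-to-next-therapy table
#'
#' Kaplan-Meier TTNT summaries in months, at one of three granularities:
#' per line number, pooled over all lines, or per specific regimen across
#' all lines (the observed range is over event durations only).
#'
#' @param lots line-of-therapy table.
#' @param cohort cohort table.
#' @param by `"by_line"`, `"all_lines"` or `"by_specific_regimen"`.
#' @param config a [journey_config()].
#' @param min_n drop groups with fewer samples than this (regimen
#'   granularity only).
#' @return data.frame of group rows with `n, n_events, median_months,`
#'   `ci_lower_months, ci_upper_months, range_min_months, range_max_months,`
#'   `raw_median_months`.
#' @export
ttnt_table <- function(lots, cohort,
                       by = c("by_line", "all_lines", "by_specific_regimen"),
                       config = journey_config(), min_n = 1L) {
  by <- match.arg(by)
  smp <- ttnt_samples(lots, cohort)
  if (nrow(smp) == 0) stop("no TTNT samples")
  groups <- switch(by,
    by_line = split(smp, smp$lot_number),
    all_lines = list(all = smp),
    by_specific_regimen = split(smp, smp$specific_regimen))
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (nrow(d) < min_n) return(NULL)
    cbind(group = g, km_summary_row(d$duration_days, d$event, config),
          stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- drug survival ---------------------------------------------------------

#' Drug survival table
#'
#' Per-drug Kaplan-Meier drug survival over all treatment episodes of all
#' recipients: when a patient has several episodes of one drug, the last
#' episode is censored and earlier episodes are events (with
#' `censor_last_policy = "near_followup"`, the last episode is censored
#' only when it ends within its gap threshold of the patient's end of
#' follow-up).  The >1-year and >2-year proportions are computed over
#' patients from cumulative on-drug days (or the longest episode, per
#' `config$duration_basis`), with thresholds 365.25 and 730.5 days.
#'
#' @param episodes episode table from [build_episodes()].
#' @param cohort cohort table; episodes of non-included patients are
#'   ignored and follow-up ends are taken from it.
#' @param catalog a `drug_catalog`.
#' @param config a [journey_config()].
#' @return data.frame per drug: `drug, n_patients, n_episodes, n_events,`
#'   `median_months, ci_lower_months, ci_upper_months, n_gt1yr, pct_gt1yr,`
#'   `n_gt2yr, pct_gt2yr`.
#' @export
drug_survival_table <- function(episodes, cohort,
                                catalog = default_catalog(),
                                config = journey_config()) {
  inc <- cohort$patient_id[cohort$included]
  ep <- episodes[episodes$patient_id %in% inc, , drop = FALSE]
  if (nrow(ep) == 0) stop("no episodes for included patients")
  fend <- setNames(cohort$followup_end, cohort$patient_id)

  rows <- lapply(split(ep, ep$drug_code), function(g) {
    smp <- drug_survival_samples(g, fend, catalog, config)
    fit_row <- km_summary_row(smp$duration_days, smp$event, config)
    per_pat <- tapply(g$duration_days, g$patient_id,
                      if (config$duration_basis == "cumulative") sum else max)
    n_gt1 <- sum(per_pat > 365.25)
    n_gt2 <- sum(per_pat > 730.5)
    data.frame(drug = g$drug_code[1],
               n_patients = length(per_pat),
               n_episodes = nrow(g),
               n_events = fit_row$n_events,
               median_months = fit_row$median_months,
               ci_lower_months = fit_row$ci_lower_months,
               ci_upper_months = fit_row$ci_upper_months,
               n_gt1yr = n_gt1, pct_gt1yr = 100 * n_gt1 / length(per_pat),
               n_gt2yr = n_gt2, pct_gt2yr = 100 * n_gt2 / length(per_pat),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$drug, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Drug survival samples for one drug
#'
#' @param drug_episodes episode rows of one drug (several patients).
#' @param followup_end named Date vector by patient id.
#' @param catalog,config see [drug_survival_table()].
#' @return data.frame `patient_id, episode_index, duration_days, event`.
#' @export
drug_survival_samples <- function(drug_episodes, followup_end,
                                  catalog = default_catalog(),
                                  config = journey_config()) {
  g <- drug_episodes[order(drug_episodes$patient_id,
                           drug_episodes$episode_index), , drop = FALSE]
  last <- !duplicated(g$patient_id, fromLast = TRUE)
  event <- !last
  if (config$censor_last_policy == "near_followup") {
    gap <- gap_threshold_days(classify_drug(catalog, g$drug_code[1]), config)
    fe <- followup_end[g$patient_id]
    ends_early <- days_between(g$end, fe) > gap
    event[last & ends_early] <- TRUE
  }
  data.frame(patient_id = g$patient_id, episode_index = g$episode_index,
             duration_days = g$duration_days, event = event,
             stringsAsFactors = FALSE)
}
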