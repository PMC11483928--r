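#' Scenario configuration for the synthetic claims generator
#'
#' Describes a simulated GPP cohort: a pathway grammar (regimen nodes with
#' duration distributions and transition probabilities), prescription
#' cadence and jitter, supplementary attachment, demographics, comorbidity
#' sprinkling and death.  The generator emits claims through the documented
#' bundle schema only, and its defaults follow the pipeline's study
#' conventions (2016-2021 window, 91/61-day gaps, 30-day combination
#' window), so ground truth is well defined under the line-of-therapy
#' rules.
#'
#' @param name scenario name.
#' @param n_patients cohort size.
#' @param nodes list of regimen nodes.  Each node is a list with `name`,
#'   `drugs` (character vector of catalog drug codes; the first is the
#'   founding drug, later ones start staggered within the combination
#'   window when `staggered = TRUE`), `duration` (either
#'   `list(dist = "exponential", median_months = m)` or
#'   `list(dist = "weibull", shape = k, scale_months = s)`), optional
#'   `supp_prob` and `supp_drug` (supplementary attachment), and optional
#'   `staggered`.
#' @param init_probs named numeric over node names; must sum to 1.
#' @param trans named list of named numeric transition probabilities
#'   (rows may sum to less than 1; the residual is "stop").
#' @param max_lines cap on the number of regimen nodes walked per patient.
#' @param transition_gap_days length-2 integer range of untreated days
#'   between consecutive regimens; `c(0, 0)` makes transitions contiguous.
#'   Consecutive regimens sharing a treatment category always get a gap
#'   above every discontinuation threshold so lines stay unambiguous.
#' @param jitter_days within-episode cadence jitter (uniform `0..jitter`),
#'   kept strictly below the discontinuation thresholds.
#' @param death_prob probability of death during follow-up (the death date
#'   truncates all claims).
#' @param p_psv,p_male,age_mean,age_sd,comorbidity demographics: psoriasis
#'   vulgaris prevalence, male proportion, age-at-index distribution, and a
#'   named probability vector of baseline ICD-10 comorbidity codes.
#' @param index_span_days index dates are sampled uniformly in
#'   `[study_start, study_start + index_span_days]`.
#' @param study_start,study_end study window.
#' @param seed default RNG seed (override in [generate_cohort()]).
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(name = "custom",
                            n_patients = 100L,
                            nodes,
                            init_probs,
                            trans = list(),
                            max_lines = 3L,
                            transition_gap_days = c(100L, 170L),
                            jitter_days = 5L,
                            death_prob = 0,
                            p_psv = 0.366,
                            p_male = 0.475,
                            age_mean = 57.2,
                            age_sd = 19.9,
                            comorbidity = c(I10 = 0.18, I21 = 0.03,
                                            E119 = 0.08, J44 = 0.04,
                                            C50 = 0.02),
                            index_span_days = 1095L,
                            study_start = "2016-01-01",
                            study_end = "2021-08-31",
                            seed = 1L) {
  node_names <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(node_names)) stop("duplicate node names")
  if (abs(sum(init_probs) - 1) > 1e-8) stop("init_probs must sum to 1")
  if (!all(names(init_probs) %in% node_names)) {
    stop("init_probs names must be node names")
  }
  for (nm in names(trans)) {
    if (!nm %in% node_names) stop("transition from unknown node: ", nm)
    p <- trans[[nm]]
    if (any(p < 0) || sum(p) > 1 + 1e-8) {
      stop("transition probabilities of '", nm,
           "' must be non-negative and sum to at most 1")
    }
    if (!all(names(p) %in% node_names)) {
      stop("transition to unknown node from: ", nm)
    }
  }
  for (nd in nodes) {
    d <- nd$duration
    if (is.null(d$dist)) stop("node '", nd$name, "': duration$dist missing")
    if (d$dist == "exponential") {
      if (is.null(d$median_months) || d$median_months <= 0) {
        stop("node '", nd$name, "': exponential needs median_months > 0")
      }
    } else if (d$dist == "weibull") {
      if (is.null(d$shape) || is.null(d$scale_months) ||
          d$shape <= 0 || d$scale_months <= 0) {
        stop("node '", nd$name, "': weibull needs shape > 0, scale_months > 0")
      }
    } else stop("node '", nd$name, "': unknown duration dist '", d$dist, "'")
  }
  if (jitter_days < 0 || jitter_days > 20) {
    stop("jitter_days must lie in 0..20 (strictly below the gap thresholds)")
  }
  structure(list(name = name, n_patients = as.integer(n_patients),
                 nodes = nodes, node_names = node_names,
                 init_probs = init_probs, trans = trans,
                 max_lines = as.integer(max_lines),
                 transition_gap_days = as.integer(transition_gap_days),
                 jitter_days = as.integer(jitter_days),
                 death_prob = death_prob, p_psv = p_psv, p_male = p_male,
                 age_mean = age_mean, age_sd = age_sd,
                 comorbidity = comorbidity,
                 index_span_days = as.integer(index_span_days),
                 study_start = as.Date(study_start),
                 study_end = as.Date(study_end),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# true median of a node's duration distribution, in days
node_median_days <- function(node, month_length = 30.4375) {
  d <- node$duration
  if (d$dist == "exponential") d$median_months * month_length
  else d$scale_months * month_length * log(2)^(1 / d$shape)
}

sample_duration_days <- function(node, month_length = 30.4375) {
  d <- node$duration
  x <- if (d$dist == "exponential") {
    rexp(1, rate = log(2) / (d$median_months * month_length))
  } else {
    rweibull(1, shape = d$shape, scale = d$scale_months * month_length)
  }
  # clamp to keep episodes well-formed; both bounds are far from the
  # preset medians so the distribution median is unaffected
  round(min(max(x, 40), 900))
}

# fill dates covering [start, end_target) with supply-day fills: cadence
# supply + U(0..jitter), final fill forced so coverage ends exactly at
# end_target (keeps all drugs of a combination ending together)
fill_dates <- function(start, end_target, supply, jitter) {
  final <- end_target - supply
  fills <- c()
  f <- start
  while (f < final) {
    fills <- c(fills, f)
    f <- f + supply + if (jitter > 0) sample.int(jitter + 1L, 1L) - 1L else 0L
  }
  sort(unique(c(fills, final)))
}

#' Named preset scenarios
#'
#' * `"simple_switching"` — monotherapy pathways of up to three lines over
#'   oral drugs and biologics; no supplementary drugs.
#' * `"combinations"` — two-drug combination regimens with staggered starts
#'   inside the combination window, supplementary attachment, and a
#'   topical-only (supplementary-only) line.
#' * `"bio_switch"` — pathways ending in a biologic-to-biologic transition
#'   with known destination classes.
#' * `"edge_cases"` — a fixed, hand-built bundle of boundary patients
#'   (single GPP diagnosis, short follow-up, death within the first year,
#'   single-prescription patient, same-day combination start, repeated
#'   episodes of one biologic) with documented expected outcomes.
#'
#' @param name preset name.
#' @param n_patients cohort size (ignored by `"edge_cases"`, which is
#'   fixed).
#' @return a `scenario_config`.
#' @export
preset_scenarios <- function(name, n_patients = 300L) {
  presets <- c("simple_switching", "combinations", "bio_switch", "edge_cases")
  if (!name %in% presets) {
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "))
  }
  exp_dur <- function(m) list(dist = "exponential", median_months = m)
  node <- function(name, drugs, duration = exp_dur(6), supp_prob = 0,
                   staggered = FALSE) {
    list(name = name, drugs = drugs, duration = duration,
         supp_prob = supp_prob, supp_drug = "topical_corticosteroid",
         staggered = staggered)
  }
  switch(name,
    simple_switching = scenario_config(
      name = name, n_patients = n_patients,
      nodes = list(
        node("etretinate", "etretinate"),
        node("cyclosporin", "cyclosporin"),
        node("secukinumab", "secukinumab", exp_dur(10)),
        node("methotrexate", "methotrexate"),
        node("guselkumab", "guselkumab", exp_dur(10))),
      init_probs = c(etretinate = 0.40, cyclosporin = 0.25,
                     secukinumab = 0.20, methotrexate = 0.15),
      trans = list(
        etretinate = c(cyclosporin = 0.35, secukinumab = 0.30),
        cyclosporin = c(etretinate = 0.30, secukinumab = 0.30),
        secukinumab = c(guselkumab = 0.40),
        methotrexate = c(etretinate = 0.30, cyclosporin = 0.30)),
      max_lines = 3L),
    combinations = scenario_config(
      name = name, n_patients = n_patients,
      nodes = list(
        node("etret_secu", c("etretinate", "secukinumab"),
             exp_dur(8), supp_prob = 0.5, staggered = TRUE),
        node("cyclo_steroid", c("cyclosporin", "systemic_corticosteroid"),
             exp_dur(4), supp_prob = 0.5, staggered = TRUE),
        node("etretinate", "etretinate", exp_dur(6), supp_prob = 0.5),
        node("topical_only", "topical_corticosteroid", exp_dur(4)),
        node("adalimumab", "adalimumab", exp_dur(10))),
      init_probs = c(etret_secu = 0.25, cyclo_steroid = 0.25,
                     etretinate = 0.30, topical_only = 0.20),
      trans = list(
        etret_secu = c(cyclo_steroid = 0.50),
        cyclo_steroid = c(etret_secu = 0.40, adalimumab = 0.20),
        etretinate = c(cyclo_steroid = 0.40, adalimumab = 0.20),
        topical_only = c(etretinate = 0.40, cyclo_steroid = 0.30)),
      max_lines = 3L),
    bio_switch = scenario_config(
      name = name, n_patients = n_patients,
      nodes = list(
        node("etretinate", "etretinate", exp_dur(4)),
        node("secukinumab", "secukinumab", exp_dur(10)),
        node("adalimumab", "adalimumab", exp_dur(10)),
        node("guselkumab", "guselkumab", exp_dur(12)),
        node("ustekinumab", "ustekinumab", exp_dur(12))),
      init_probs = c(etretinate = 0.50, secukinumab = 0.25,
                     adalimumab = 0.25),
      trans = list(
        etretinate = c(secukinumab = 0.50, adalimumab = 0.50),
        secukinumab = c(guselkumab = 0.60, adalimumab = 0.40),
        adalimumab = c(secukinumab = 0.50, ustekinumab = 0.50)),
      max_lines = 3L),
    edge_cases = scenario_config(
      name = name, n_patients = 8L,
      nodes = list(node("etretinate", "etretinate")),
      init_probs = c(etretinate = 1))
  )
}

#' Generate a synthetic claims bundle with known ground truth
#'
#' Walks each patient through the scenario's pathway grammar, emitting
#' prescriptions at the stated cadence over every true regimen interval,
#' at least two confirmed GPP (L40.1) diagnoses, regular follow-up visit
#' records up to the intended end of follow-up, baseline comorbidity codes
#' and deaths.  Deterministic for a fixed seed.
#'
#' @param config a [scenario_config()] or [preset_scenarios()] result.
#' @param seed optional integer overriding `config$seed`.
#' @param catalog a `drug_catalog` (supplies supplies/coverage durations).
#' @return a list with `bundle` (a `claims_bundle`) and `truth`, where
#'   `truth` holds `eligibility`, `episodes`, `lots`, `ttnt` (all
#'   data.frames keyed by patient), and `node_median_days`.
#' @export
generate_cohort <- function(config, seed = NULL,
                            catalog = default_catalog()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed %||% config$seed, kind = "Mersenne-Twister",
           sample.kind = "Rejection")
  if (config$name == "edge_cases") return(generate_edge_cases(config, catalog))

  entries <- catalog$entries
  supp_of <- function(code) entries$is_supplementary[match(code, entries$drug_code)]
  cat_of <- function(code) entries$category2[match(code, entries$drug_code)]
  cover_of <- function(code) entries$default_coverage_days[match(code, entries$drug_code)]

  pats <- dxs <- rxs <- eps <- lots <- list()
  elig <- list()
  study_start <- config$study_start
  study_end <- config$study_end

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", i)
    index <- study_start + sample.int(config$index_span_days, 1L)
    age <- round(min(max(rnorm(1, config$age_mean, config$age_sd), 18), 95))
    sex <- if (runif(1) < config$p_male) "male" else "female"
    birth_year <- as.integer(format(index, "%Y")) - age
    death <- as.Date(NA)
    if (runif(1) < config$death_prob) {
      death <- index + round(runif(1, 60, 1500))
      if (death > study_end) death <- as.Date(NA)
    }
    fend_planned <- min(c(study_end, death), na.rm = TRUE)

    # pathway walk (lot fields accumulated as parallel vectors)
    lot_start <- integer(0); lot_end <- integer(0)
    lot_spec <- character(0); lot_gen <- character(0)
    drug_fills <- list()  # per (regimen, drug): fill dates + supply flag
    nodeset <- setNames(config$nodes, config$node_names)
    cur_node <- sample(names(config$init_probs), 1L,
                       prob = config$init_probs)
    t <- index + sample.int(15L, 1L) - 1L
    line <- 0L
    while (!is.null(cur_node) && line < config$max_lines) {
      nd <- nodeset[[cur_node]]
      dur <- sample_duration_days(nd)
      main_drugs <- nd$drugs[!supp_of(nd$drugs)]
      supp_only <- length(main_drugs) == 0L
      reg_drugs <- nd$drugs
      starts <- rep(t, length(reg_drugs))
      if (isTRUE(nd$staggered) && length(reg_drugs) > 1L) {
        starts[-1] <- t + sample(7:21, length(reg_drugs) - 1L,
                                 replace = TRUE)
      }
      nominal_end <- t + dur
      end_target <- max(c(nominal_end,
                          starts + cover_of(reg_drugs)))
      # a regimen that cannot complete inside follow-up is not started
      if (as.integer(end_target) + 30L > as.integer(fend_planned)) break
      attach_supp <- !supp_only && runif(1) < (nd$supp_prob %||% 0)

      for (k in seq_along(reg_drugs)) {
        code <- reg_drugs[k]
        supply <- cover_of(code)
        fills <- fill_dates(as.integer(starts[k]), as.integer(end_target),
                            supply, config$jitter_days)
        drug_fills[[length(drug_fills) + 1L]] <- list(
          code = code, fills = fills, supply = supply,
          oral = entries$gap_class[match(code, entries$drug_code)] != "biologic")
      }
      if (attach_supp) {
        scode <- nd$supp_drug
        ssupply <- cover_of(scode)
        sfills <- fill_dates(as.integer(t), as.integer(end_target),
                             ssupply, config$jitter_days)
        drug_fills[[length(drug_fills) + 1L]] <- list(
          code = scode, fills = sfills, supply = ssupply, oral = TRUE)
      }

      line <- line + 1L
      cats <- unique(cat_of(reg_drugs))
      if (supp_only) {
        general <- cats[which.min(catalog$priority_table[cats])]
        specific <- if (length(cats) > 1L)
          paste0(general, " + supplementary drug") else general
      } else {
        main_cats <- unique(cat_of(main_drugs))
        general <- main_cats[which.min(catalog$priority_table[main_cats])]
        specific <- paste(sort_c(main_cats), collapse = " + ")
        if (attach_supp) specific <- paste0(specific, " + supplementary drug")
      }
      lot_start <- c(lot_start, as.integer(min(starts)))
      lot_end <- c(lot_end, as.integer(end_target))
      lot_spec <- c(lot_spec, specific)
      lot_gen <- c(lot_gen, general)

      # next node
      p <- config$trans[[cur_node]]
      nxt <- NULL
      if (!is.null(p) && length(p)) {
        u <- runif(1)
        cum <- cumsum(p)
        j <- which(u <= cum)
        if (length(j)) nxt <- names(p)[min(j)]
      }
      if (is.null(nxt)) break
      nxt_cats <- cat_of(nodeset[[nxt]]$drugs)
      gap_lo <- config$transition_gap_days[1]
      gap_hi <- config$transition_gap_days[2]
      if (length(intersect(cats, nxt_cats))) {
        gap_lo <- max(gap_lo, 100L); gap_hi <- max(gap_hi, 170L)
      }
      gap <- if (gap_hi > gap_lo) {
        gap_lo + sample.int(gap_hi - gap_lo + 1L, 1L) - 1L
      } else gap_lo
      t <- as.Date(as.integer(end_target) + gap, origin = "1970-01-01")
      cur_node <- nxt
    }

    # follow-up visit records up to the intended end of follow-up
    visit_dates <- seq(from = index, to = fend_planned, by = 60)
    visit_dates <- unique(c(visit_dates, fend_planned))
    fend_actual <- max(visit_dates)

    # diagnoses (as parallel vectors; one data.frame per patient)
    dx_code <- c("L40.1", "L40.1", rep("Z00.0", length(visit_dates)))
    dx_date <- c(index, index + 14L, visit_dates)
    if (runif(1) < config$p_psv) {
      dx_code <- c(dx_code, "L40.0")
      dx_date <- c(dx_date, index - sample.int(300L, 1L))
    }
    for (cm in names(config$comorbidity)) {
      if (runif(1) < config$comorbidity[[cm]]) {
        dx_code <- c(dx_code, cm)
        dx_date <- c(dx_date, index - sample(30:300, 1L))
      }
    }
    dx <- data.frame(patient_id = pid, code = dx_code, date = dx_date,
                     confirmed = TRUE, stringsAsFactors = FALSE)

    # prescriptions + ground-truth episodes
    rx_code <- character(0); rx_date <- integer(0); rx_supply <- integer(0)
    ep_code <- character(0); ep_idx <- integer(0)
    ep_start <- integer(0); ep_end <- integer(0); ep_last <- logical(0)
    if (length(drug_fills)) {
      by_code <- split(drug_fills, vapply(drug_fills, `[[`, character(1),
                                          "code"))
      for (code in sort_c(names(by_code))) {
        blocks <- by_code[[code]]
        blocks <- blocks[order(vapply(blocks, function(b) b$fills[1],
                                      numeric(1)))]
        for (bi in seq_along(blocks)) {
          b <- blocks[[bi]]
          rx_code <- c(rx_code, rep(code, length(b$fills)))
          rx_date <- c(rx_date, b$fills)
          rx_supply <- c(rx_supply,
                         rep(if (b$oral) b$supply else NA_integer_,
                             length(b$fills)))
          ep_code <- c(ep_code, code)
          ep_idx <- c(ep_idx, bi)
          ep_start <- c(ep_start, b$fills[1])
          ep_end <- c(ep_end, max(b$fills) + b$supply)
          ep_last <- c(ep_last, bi == length(blocks))
        }
      }
    }

    pats[[i]] <- data.frame(patient_id = pid, sex = sex,
                            birth_year = birth_year, death_date = death,
                            stringsAsFactors = FALSE)
    dxs[[i]] <- dx
    if (length(rx_code)) {
      rxs[[i]] <- data.frame(
        patient_id = pid, drug_code = rx_code,
        date = as.Date(rx_date, origin = "1970-01-01"),
        days_supply = rx_supply, stringsAsFactors = FALSE)
    }
    if (length(ep_code)) {
      eps[[i]] <- data.frame(
        patient_id = pid, drug_code = ep_code, episode_index = ep_idx,
        start = as.Date(ep_start, origin = "1970-01-01"),
        end = as.Date(ep_end, origin = "1970-01-01"),
        is_last = ep_last, stringsAsFactors = FALSE)
    }
    if (length(lot_start)) {
      lots[[i]] <- data.frame(
        patient_id = pid, lot_number = seq_along(lot_start),
        start = as.Date(lot_start, origin = "1970-01-01"),
        end = as.Date(lot_end, origin = "1970-01-01"),
        specific_regimen = lot_spec, general_regimen = lot_gen,
        is_last = seq_along(lot_start) == length(lot_start),
        stringsAsFactors = FALSE)
    }
    elig[[i]] <- data.frame(patient_id = pid, included = TRUE,
                            reason = "ok", index_date = index,
                            followup_end = fend_actual,
                            stringsAsFactors = FALSE)
  }

  assemble_truth(config, catalog, pats, dxs, rxs, eps, lots, elig)
}

# shared assembly: sort tables deterministically, compute TTNT truth
assemble_truth <- function(config, catalog, pats, dxs, rxs, eps, lots, elig) {
  patients <- do.call(rbind, pats)
  diagnoses <- do.call(rbind, dxs)
  prescriptions <- if (length(rxs)) do.call(rbind, rxs) else
    data.frame(patient_id = character(0), drug_code = character(0),
               date = as.Date(character(0)), days_supply = integer(0))
  diagnoses <- diagnoses[order(diagnoses$patient_id, diagnoses$date,
                               diagnoses$code, method = "radix"), ]
  prescriptions <- prescriptions[order(prescriptions$patient_id,
                                       prescriptions$drug_code,
                                       prescriptions$date,
                                       method = "radix"), ]
  bundle <- claims_bundle(patients, diagnoses, prescriptions,
                          c(config$study_start, config$study_end))

  truth_lots <- if (length(lots)) do.call(rbind, lots) else
    data.frame(patient_id = character(0), lot_number = integer(0),
               start = as.Date(character(0)), end = as.Date(character(0)),
               specific_regimen = character(0),
               general_regimen = character(0), is_last = logical(0))
  truth_eps <- if (length(eps)) do.call(rbind, eps) else
    data.frame(patient_id = character(0), drug_code = character(0),
               episode_index = integer(0), start = as.Date(character(0)),
               end = as.Date(character(0)), is_last = logical(0))
  eligibility <- do.call(rbind, elig)

  fend <- setNames(eligibility$followup_end, eligibility$patient_id)
  ttnt <- if (nrow(truth_lots)) {
    do.call(rbind, lapply(split(truth_lots, truth_lots$patient_id),
      function(g) {
        g <- g[order(g$lot_number), ]
        n <- nrow(g)
        nxt <- c(g$start[-1], as.Date(NA))
        dur <- ifelse(seq_len(n) < n, days_between(g$start, nxt),
                      days_between(g$start, fend[[g$patient_id[1]]]))
        data.frame(patient_id = g$patient_id, lot_number = g$lot_number,
                   duration_days = as.integer(dur), event = seq_len(n) < n,
                   stringsAsFactors = FALSE)
      }))
  } else {
    data.frame(patient_id = character(0), lot_number = integer(0),
               duration_days = integer(0), event = logical(0))
  }
  rownames(truth_lots) <- rownames(truth_eps) <- rownames(ttnt) <- NULL
  truth_eps <- truth_eps[order(truth_eps$patient_id, truth_eps$drug_code,
                               truth_eps$episode_index, method = "radix"), ]
  rownames(truth_eps) <- NULL

  medians <- vapply(config$nodes, node_median_days, numeric(1))
  names(medians) <- config$node_names

  list(bundle = bundle,
       truth = list(eligibility = eligibility, episodes = truth_eps,
                    lots = truth_lots, ttnt = ttnt,
                    node_median_days = medians))
}

# fixed boundary-case patients with documented expected outcomes
generate_edge_cases <- function(config, catalog) {
  entries <- catalog$entries
  cover_of <- function(code) entries$default_coverage_days[match(code, entries$drug_code)]
  study_end <- config$study_end
  pats <- dxs <- rxs <- eps <- lots <- elig <- list()
  add_patient <- function(pid, sex, birth_year, death = as.Date(NA)) {
    pats[[length(pats) + 1L]] <<- data.frame(
      patient_id = pid, sex = sex, birth_year = birth_year,
      death_date = death, stringsAsFactors = FALSE)
  }
  add_dx <- function(pid, code, dates, confirmed = TRUE) {
    dxs[[length(dxs) + 1L]] <<- data.frame(
      patient_id = pid, code = code, date = as.Date(dates),
      confirmed = confirmed, stringsAsFactors = FALSE)
  }
  visits <- function(pid, from, to) {
    d <- unique(c(seq(as.Date(from), as.Date(to), by = 60), as.Date(to)))
    add_dx(pid, "Z00.0", d)
    max(d)
  }
  # contiguous fills with exact coverage end
  add_course <- function(pid, code, start, end, ep_index = 1L,
                         is_last = TRUE) {
    supply <- cover_of(code)
    f <- fill_dates(as.integer(as.Date(start)), as.integer(as.Date(end)),
                    supply, jitter = 0L)
    oral <- entries$gap_class[match(code, entries$drug_code)] != "biologic"
    rxs[[length(rxs) + 1L]] <<- data.frame(
      patient_id = pid, drug_code = code,
      date = as.Date(f, origin = "1970-01-01"),
      days_supply = if (oral) supply else NA_integer_,
      stringsAsFactors = FALSE)
    eps[[length(eps) + 1L]] <<- data.frame(
      patient_id = pid, drug_code = code, episode_index = ep_index,
      start = as.Date(start), end = as.Date(end), is_last = is_last,
      stringsAsFactors = FALSE)
  }
  add_lot <- function(pid, n, start, end, specific, general, is_last) {
    lots[[length(lots) + 1L]] <<- data.frame(
      patient_id = pid, lot_number = n, start = as.Date(start),
      end = as.Date(end), specific_regimen = specific,
      general_regimen = general, is_last = is_last, stringsAsFactors = FALSE)
  }
  add_elig <- function(pid, included, reason, index = as.Date(NA),
                       fend = as.Date(NA)) {
    elig[[length(elig) + 1L]] <<- data.frame(
      patient_id = pid, included = included, reason = reason,
      index_date = as.Date(index), followup_end = as.Date(fend),
      stringsAsFactors = FALSE)
  }

  # E01: exactly one confirmed GPP diagnosis -> excluded
  add_patient("E01", "female", 1960)
  add_dx("E01", "L40.1", "2017-02-01")
  visits("E01", "2017-02-01", "2019-02-01")
  add_course("E01", "etretinate", "2017-03-01", "2017-05-30")
  add_elig("E01", FALSE, "single_gpp_diagnosis")

  # E02: < 1 year of follow-up, alive -> excluded
  add_patient("E02", "male", 1975)
  add_dx("E02", "L40.1", c("2021-02-01", "2021-02-15"))
  visits("E02", "2021-02-01", study_end)
  add_course("E02", "etretinate", "2021-02-10", "2021-05-11")
  add_elig("E02", FALSE, "insufficient_followup")

  # E03: died within the first year -> included despite short follow-up
  add_patient("E03", "male", 1950, death = as.Date("2017-08-15"))
  add_dx("E03", "L40.1", c("2017-03-01", "2017-03-15"))
  f3 <- visits("E03", "2017-03-01", "2017-08-15")
  add_course("E03", "cyclosporin", "2017-03-01", "2017-07-29")
  add_lot("E03", 1L, "2017-03-01", "2017-07-29", "Cyclosporin",
          "Cyclosporin", TRUE)
  add_elig("E03", TRUE, "ok", "2017-03-01", f3)

  # E04: single prescription -> one episode, one censored line
  add_patient("E04", "female", 1980)
  add_dx("E04", "L40.1", c("2018-01-10", "2018-01-24"))
  f4 <- visits("E04", "2018-01-10", study_end)
  add_course("E04", "etretinate", "2018-01-20", "2018-02-19")
  add_lot("E04", 1L, "2018-01-20", "2018-02-19", "Etretinate",
          "Etretinate", TRUE)
  add_elig("E04", TRUE, "ok", "2018-01-10", f4)

  # E05: two mains starting the same day -> one combination line
  add_patient("E05", "male", 1965)
  add_dx("E05", "L40.1", c("2018-03-01", "2018-03-20"))
  f5 <- visits("E05", "2018-03-01", study_end)
  add_course("E05", "etretinate", "2018-03-05", "2018-09-05")
  add_course("E05", "cyclosporin", "2018-03-05", "2018-09-05")
  add_lot("E05", 1L, "2018-03-05", "2018-09-05",
          "Cyclosporin + Etretinate", "Etretinate", TRUE)
  add_elig("E05", TRUE, "ok", "2018-03-01", f5)

  # E06: two episodes of one biologic (lapse above the 3-month gap);
  # first episode is an event, last is censored; the re-start opens a
  # new line even though the regimen is identical
  add_patient("E06", "female", 1990)
  add_dx("E06", "L40.1", c("2016-06-01", "2016-06-20"))
  f6 <- visits("E06", "2016-06-01", study_end)
  add_course("E06", "secukinumab", "2016-06-10", "2016-12-10",
             ep_index = 1L, is_last = FALSE)
  add_course("E06", "secukinumab", "2017-06-01", "2017-12-01",
             ep_index = 2L, is_last = TRUE)
  add_lot("E06", 1L, "2016-06-10", "2016-12-10", "IL-17 inhibitors",
          "IL-17 inhibitors", FALSE)
  add_lot("E06", 2L, "2017-06-01", "2017-12-01", "IL-17 inhibitors",
          "IL-17 inhibitors", TRUE)
  add_elig("E06", TRUE, "ok", "2016-06-01", f6)

  # E07: only unconfirmed GPP diagnoses -> excluded (unclear history)
  add_patient("E07", "unknown", 1970)
  add_dx("E07", "L40.1", c("2018-05-01", "2018-06-01"), confirmed = FALSE)
  visits("E07", "2018-05-01", "2020-05-01")
  add_elig("E07", FALSE, "unclear_history")

  # E08: three-line journey ending in a biologic-to-biologic switch
  add_patient("E08", "male", 1955)
  add_dx("E08", "L40.1", c("2016-04-01", "2016-04-20"))
  f8 <- visits("E08", "2016-04-01", study_end)
  add_course("E08", "etretinate", "2016-04-10", "2016-10-10")
  add_course("E08", "secukinumab", "2017-02-07", "2017-08-07")
  add_course("E08", "guselkumab", "2017-12-05", "2018-06-05")
  add_lot("E08", 1L, "2016-04-10", "2016-10-10", "Etretinate",
          "Etretinate", FALSE)
  add_lot("E08", 2L, "2017-02-07", "2017-08-07", "IL-17 inhibitors",
          "IL-17 inhibitors", FALSE)
  add_lot("E08", 3L, "2017-12-05", "2018-06-05", "IL-23 inhibitors",
          "IL-23 inhibitors", TRUE)
  add_elig("E08", TRUE, "ok", "2016-04-01", f8)

  assemble_truth(config, catalog, pats, dxs, rxs, eps, lots, elig)
}

#' Inject bounded noise into a generated bundle
#'
#' Two labelled noise kinds:
#' * `jitter_days = j` (sub-threshold): every non-first fill of every
#'   patient-drug is delayed by `0..j` days.  `j` is capped at 40 days so
#'   that, together with the generator's cadence jitter, no lapse can reach
#'   the 61-day oral threshold; derived episode counts are unchanged.
#' * `split = list(gap_days = g)` (supra-threshold): picks the first (by
#'   patient id) oral patient-drug course with at least four fills and
#'   shifts its second half `g` days later, splitting one episode in two;
#'   `g` must exceed the drug's gap threshold.  The ground-truth episode
#'   table is updated; lines and TTNT truth are marked stale.
#'
#' @param bundle a generated `claims_bundle`.
#' @param truth the matching ground truth.
#' @param noise list with `jitter_days` and/or `split`; an empty list
#'   returns the input unchanged.
#' @param seed RNG seed for the jitter draws.
#' @param catalog,config catalog and conventions.
#' @return list `bundle`, `truth`.
#' @export
inject_noise <- function(bundle, truth, noise = list(), seed = 1L,
                         catalog = default_catalog(),
                         config = journey_config()) {
  if (length(noise) == 0) return(list(bundle = bundle, truth = truth))
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  rx <- bundle$prescriptions

  if (!is.null(noise$jitter_days)) {
    j <- as.integer(noise$jitter_days)
    if (j > 40L) {
      stop("jitter_days > 40 can cross a discontinuation threshold; ",
           "relabel as a split (supra-threshold) injection")
    }
    key <- paste(rx$patient_id, rx$drug_code, sep = "\r")
    o <- order(key, rx$date, method = "radix")
    rx <- rx[o, ]
    key <- key[o]
    not_first <- duplicated(key)
    delay <- integer(nrow(rx))
    delay[not_first] <- sample.int(j + 1L, sum(not_first),
                                   replace = TRUE) - 1L
    rx$date <- rx$date + delay
  }

  if (!is.null(noise$split)) {
    g <- as.integer(noise$split$gap_days %||% 90L)
    key <- paste(rx$patient_id, rx$drug_code, sep = "\r")
    counts <- table(key)
    oral <- vapply(strsplit(names(counts), "\r"), function(kk) {
      classify_drug(catalog, kk[2])$gap_class == "oral"
    }, logical(1))
    cand <- sort_c(names(counts)[counts >= 4 & oral])
    if (length(cand) == 0) stop("no oral course with >= 4 fills to split")
    target <- strsplit(cand[1], "\r")[[1]]
    thr <- gap_threshold_days(classify_drug(catalog, target[2]), config)
    if (g <= thr) {
      stop("split gap_days (", g, ") does not exceed the drug's ",
           "discontinuation threshold (", thr, " days)")
    }
    sel <- which(rx$patient_id == target[1] & rx$drug_code == target[2])
    sel <- sel[order(rx$date[sel])]
    half <- sel[seq(ceiling(length(sel) / 2) + 1L, length(sel))]
    rx$date[half] <- rx$date[half] + g

    # recompute ground-truth episodes of the split course
    ep <- truth$episodes
    keep <- !(ep$patient_id == target[1] & ep$drug_code == target[2])
    supply <- classify_drug(catalog, target[2])$default_coverage_days
    ds <- rx$days_supply[sel]
    ds[is.na(ds)] <- supply
    first_half <- setdiff(sel, half)
    new_eps <- data.frame(
      patient_id = target[1], drug_code = target[2],
      episode_index = 1:2,
      start = c(min(rx$date[first_half]), min(rx$date[half])),
      end = c(max(rx$date[first_half] + ds[match(first_half, sel)]),
              max(rx$date[half] + ds[match(half, sel)])),
      is_last = c(FALSE, TRUE), stringsAsFactors = FALSE)
    ep <- rbind(ep[keep, ], new_eps)
    ep <- ep[order(ep$patient_id, ep$drug_code, ep$episode_index,
                   method = "radix"), ]
    rownames(ep) <- NULL
    truth$episodes <- ep
    truth$lots_stale <- TRUE
  }

  rx <- rx[order(rx$patient_id, rx$drug_code, rx$date, method = "radix"), ]
  bundle$prescriptions <- rx
  rownames(bundle$prescriptions) <- NULL
  list(bundle = bundle, truth = truth)
}
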