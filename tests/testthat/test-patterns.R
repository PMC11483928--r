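mk_cohort <- function(ids, psv = FALSE, a65 = FALSE, a75 = FALSE) {
  data.frame(patient_id = ids, included = TRUE, reason = "ok",
             index_date = as.Date("2017-01-01"),
             followup_end = as.Date("2020-01-01"),
             age_at_index = 50L, cci_score = 0L,
             has_psv = psv, age_ge65 = a65, age_ge75 = a75,
             stringsAsFactors = FALSE)
}

mk_lots <- function(pid, regimens) {
  n <- length(regimens)
  data.frame(patient_id = pid, lot_number = seq_len(n),
             start = as.Date("2017-02-01") + 180 * (seq_len(n) - 1),
             end = as.Date("2017-02-01") + 180 * (seq_len(n) - 1) + 150,
             specific_regimen = regimens, general_regimen = regimens,
             is_last = seq_len(n) == n, stringsAsFactors = FALSE)
}

test_that("sankey flows count transitions with an explicit sink", {
  lots <- rbind(mk_lots("P1", c("Etretinate", "Cyclosporin")),
                mk_lots("P2", c("Etretinate", "Cyclosporin")),
                mk_lots("P3", "Etretinate"))
  cohort <- mk_cohort(c("P1", "P2", "P3"))
  fl <- sankey_flows(lots, cohort, depth = 2)
  expect_equal(fl$n[fl$from == "Etretinate" & fl$to == "Cyclosporin"], 2L)
  expect_equal(fl$n[fl$from == "Etretinate" & fl$to == "No further therapy"],
               1L)
  # conservation: outflow at line 1 equals patients with >= 1 line
  expect_equal(sum(fl$n[fl$line == 1]), 3L)
  expect_error(sankey_flows(lots, cohort, depth = 1), "depth")
  # empty cohort -> empty flows
  fl0 <- sankey_flows(lots[0, ], cohort, depth = 3)
  expect_equal(nrow(fl0), 0L)
})

test_that("sankey conservation holds per regimen and line on a preset", {
  g <- generate_cohort(preset_scenarios("simple_switching", 60), seed = 3)
  res <- run_patient_journey(g$bundle)
  fl <- res$sankey
  for (k in unique(fl$line)) {
    at_k <- res$lots[res$lots$lot_number == k, ]
    for (reg in unique(at_k$general_regimen)) {
      expect_equal(sum(fl$n[fl$line == k & fl$from == reg]),
                   sum(at_k$general_regimen == reg))
    }
  }
})

test_that("disjoint strata partition the unstratified sankey counts", {
  g <- generate_cohort(preset_scenarios("simple_switching", 80), seed = 4)
  res <- run_patient_journey(g$bundle)
  f_all <- sankey_flows(res$lots, res$cohort, stratum = "all")
  f_psv <- sankey_flows(res$lots, res$cohort, stratum = "psv")
  f_no <- sankey_flows(res$lots, res$cohort, stratum = "no_psv")
  key <- function(f) paste(f$line, f$from, f$to, sep = "\r")
  tot <- tapply(c(f_psv$n, f_no$n), c(key(f_psv), key(f_no)), sum)
  expect_equal(as.vector(tot[key(f_all)]), f_all$n)
})

test_that("combination frequencies use the one-day overlap rule", {
  ep <- function(pid, drug, s, e) {
    data.frame(patient_id = pid, drug_code = drug, episode_index = 1L,
               start = as.Date(s), end = as.Date(e),
               duration_days = as.integer(as.Date(e) - as.Date(s)),
               n_prescriptions = 1L, is_last = TRUE,
               category2 = classify_drug(default_catalog(), drug)$category2,
               stringsAsFactors = FALSE)
  }
  # one of two secukinumab patients overlaps systemic corticosteroids
  eps <- rbind(
    ep("P1", "secukinumab", "2018-01-01", "2018-06-01"),
    ep("P1", "systemic_corticosteroid", "2018-03-01", "2018-04-01"),
    ep("P2", "secukinumab", "2018-01-01", "2018-06-01"))
  cohort <- mk_cohort(c("P1", "P2"))
  cf <- combination_frequencies(eps, cohort, anchors = "IL-17 inhibitors")
  row <- cf[cf$partner == "Corticosteroids", ]
  expect_equal(row$n_exposed, 2L)
  expect_equal(row$pct, 50)

  # an overlap of exactly one day counts; zero days does not
  eps2 <- rbind(ep("P1", "secukinumab", "2018-01-01", "2018-02-01"),
                ep("P1", "etretinate", "2018-01-31", "2018-03-01"))
  cf2 <- combination_frequencies(eps2, mk_cohort("P1"),
                                 anchors = "IL-17 inhibitors")
  expect_equal(cf2$pct[cf2$partner == "Etretinate"], 100)
  eps3 <- rbind(ep("P1", "secukinumab", "2018-01-01", "2018-02-01"),
                ep("P1", "etretinate", "2018-02-01", "2018-03-01"))
  cf3 <- combination_frequencies(eps3, mk_cohort("P1"),
                                 anchors = "IL-17 inhibitors")
  expect_equal(cf3$pct[cf3$partner == "Etretinate"], 0)

  expect_error(combination_frequencies(eps, cohort, anchors = "Nonsense"),
               "unknown anchor")
})

test_that("bio-switching takes the first different biologic after the last episode", {
  ep <- function(pid, drug, s, e, idx = 1L, last = TRUE) {
    data.frame(patient_id = pid, drug_code = drug, episode_index = idx,
               start = as.Date(s), end = as.Date(e),
               duration_days = as.integer(as.Date(e) - as.Date(s)),
               n_prescriptions = 1L, is_last = last,
               category2 = classify_drug(default_catalog(), drug)$category2,
               stringsAsFactors = FALSE)
  }
  cohort <- mk_cohort(c("P1", "P2", "P3"))
  eps <- rbind(
    # P1: secukinumab then guselkumab -> switch to IL-23
    ep("P1", "secukinumab", "2017-02-01", "2017-11-28"),
    ep("P1", "guselkumab", "2018-01-07", "2018-07-01"),
    # P2: secukinumab, nothing after -> non-switcher
    ep("P2", "secukinumab", "2017-02-01", "2017-11-28"),
    # P3: secukinumab then adalimumab (earlier) and guselkumab (later)
    ep("P3", "secukinumab", "2017-02-01", "2017-11-28"),
    ep("P3", "adalimumab", "2018-01-15", "2018-06-01"),
    ep("P3", "guselkumab", "2018-03-01", "2018-09-01"))
  sw <- bioswitch_matrix(eps, cohort)
  secu <- sw[sw$biologic == "secukinumab", ]
  expect_equal(unique(secu$n_treated), 3L)
  expect_equal(unique(secu$n_switched), 2L)
  expect_equal(secu$n_dest[secu$dest_class == "IL-23 inhibitors"], 1L)
  expect_equal(secu$n_dest[secu$dest_class == "TNF-alpha inhibitors"], 1L)
  # destination counts sum to n_switched for every index biologic
  for (b in unique(sw$biologic)) {
    expect_equal(sum(sw$n_dest[sw$biologic == b]),
                 unique(sw$n_switched[sw$biologic == b]))
  }
  # restarting the same biologic is not a switch
  eps_r <- rbind(ep("P1", "secukinumab", "2017-02-01", "2017-11-28",
                    idx = 1L, last = FALSE),
                 ep("P1", "secukinumab", "2018-03-01", "2018-09-01",
                    idx = 2L, last = TRUE))
  sw_r <- bioswitch_matrix(eps_r, cohort)
  expect_equal(sw_r$n_switched[sw_r$biologic == "secukinumab"], 0L)
})
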