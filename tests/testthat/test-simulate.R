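test_that("generation is deterministic for a fixed seed", {
  sc <- preset_scenarios("simple_switching", n_patients = 25)
  g1 <- generate_cohort(sc, seed = 7)
  g2 <- generate_cohort(sc, seed = 7)
  expect_identical(g1$bundle$patients, g2$bundle$patients)
  expect_identical(g1$bundle$diagnoses, g2$bundle$diagnoses)
  expect_identical(g1$bundle$prescriptions, g2$bundle$prescriptions)
  expect_identical(g1$truth, g2$truth)
  # and the emitted CSV files are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_claims_bundle(g1$bundle, d1)
  write_claims_bundle(g2$bundle, d2)
  for (f in c("patients.csv", "diagnoses.csv", "prescriptions.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # a different seed changes the data
  g3 <- generate_cohort(sc, seed = 8)
  expect_false(identical(g1$bundle$prescriptions, g3$bundle$prescriptions))
})

test_that("scenario validation rejects malformed configurations", {
  nd <- list(list(name = "a", drugs = "etretinate",
                  duration = list(dist = "exponential", median_months = 6)))
  expect_error(scenario_config(nodes = nd, init_probs = c(a = 0.5)),
               "sum to 1")
  expect_error(scenario_config(nodes = nd, init_probs = c(b = 1)),
               "node names")
  expect_error(scenario_config(nodes = nd, init_probs = c(a = 1),
                               trans = list(a = c(a = 0.7, b = 0.6))),
               "at most 1|unknown node")
  bad_dur <- nd
  bad_dur[[1]]$duration <- list(dist = "exponential", median_months = -2)
  expect_error(scenario_config(nodes = bad_dur, init_probs = c(a = 1)),
               "median_months")
  bad_w <- nd
  bad_w[[1]]$duration <- list(dist = "weibull", shape = 0, scale_months = 3)
  expect_error(scenario_config(nodes = bad_w, init_probs = c(a = 1)),
               "weibull")
  expect_error(scenario_config(nodes = nd, init_probs = c(a = 1),
                               jitter_days = 30), "jitter")
  expect_error(preset_scenarios("no_such_preset"), "simple_switching")
})

test_that("edge-case preset ships the documented boundary patients", {
  g <- generate_cohort(preset_scenarios("edge_cases"), seed = 1)
  b <- g$bundle
  # a patient with exactly one confirmed GPP diagnosis
  gpp <- b$diagnoses[normalize_code(b$diagnoses$code) == "L401" &
                       b$diagnoses$confirmed, ]
  n_gpp <- table(gpp$patient_id)
  expect_true(any(n_gpp == 1))
  # a patient who died within the first year
  expect_true(any(!is.na(b$patients$death_date)))
  # a same-day combination start
  rx <- b$prescriptions
  first_fill <- tapply(as.integer(rx$date),
                       paste(rx$patient_id, rx$drug_code, sep = "\r"), min)
  ids <- sub("\r.*", "", names(first_fill))
  same_day <- tapply(first_fill, ids, function(x) anyDuplicated(x) > 0)
  expect_true(any(same_day))
  # truth marks exactly the documented inclusion decisions
  el <- g$truth$eligibility
  expect_setequal(el$reason[!el$included],
                  c("single_gpp_diagnosis", "insufficient_followup",
                    "unclear_history"))
})

test_that("sub-threshold jitter never changes derived episode counts", {
  g <- generate_cohort(preset_scenarios("simple_switching", 25), seed = 2)
  ep0 <- build_episodes(g$bundle)
  noisy <- inject_noise(g$bundle, g$truth, list(jitter_days = 10), seed = 5)
  ep1 <- build_episodes(noisy$bundle)
  count <- function(ep) {
    tapply(ep$episode_index, paste(ep$patient_id, ep$drug_code, sep = "\r"),
           max)
  }
  expect_identical(count(ep1), count(ep0))
  # an unlabelled threshold-crossing jitter is rejected
  expect_error(inject_noise(g$bundle, g$truth, list(jitter_days = 50)),
               "threshold")
  # an empty noise configuration is the identity
  same <- inject_noise(g$bundle, g$truth, list())
  expect_identical(same$bundle$prescriptions, g$bundle$prescriptions)
})

test_that("an injected supra-threshold gap splits exactly one episode", {
  g <- generate_cohort(preset_scenarios("simple_switching", 25), seed = 2)
  ep0 <- build_episodes(g$bundle)
  noisy <- inject_noise(g$bundle, g$truth, list(split = list(gap_days = 90)),
                        seed = 5)
  ep1 <- build_episodes(noisy$bundle)
  expect_equal(nrow(ep1), nrow(ep0) + 1L)
  # the updated ground truth matches the re-derived episodes
  cols <- c("patient_id", "drug_code", "episode_index", "start", "end",
            "is_last")
  d <- ep1[, cols]; t <- noisy$truth$episodes[, cols]
  rownames(d) <- rownames(t) <- NULL
  expect_equal(d, t)
  # a "split" that does not exceed the threshold is rejected
  expect_error(inject_noise(g$bundle, g$truth,
                            list(split = list(gap_days = 30))),
               "does not exceed")
})

test_that("generated bundles pass validation and eligibility by design", {
  for (nm in c("simple_switching", "combinations", "bio_switch")) {
    g <- generate_cohort(preset_scenarios(nm, 20), seed = 6)
    expect_equal(validate_bundle(g$bundle)$error_count, 0)
    cohort <- build_cohort(g$bundle)
    expect_true(all(cohort$included))
    # the documented index/follow-up match the generator's intent
    m <- merge(cohort, g$truth$eligibility, by = "patient_id",
               suffixes = c(".d", ".t"))
    expect_equal(m$index_date.d, m$index_date.t)
    expect_equal(m$followup_end.d, m$followup_end.t)
  }
})

test_that("derived TTNT medians recover the configured distribution", {
  # one-line pathway with a contiguous transition to a second regimen:
  # first-line TTNT equals the configured exponential duration
  sc <- scenario_config(
    name = "km_recovery", n_patients = 400,
    nodes = list(
      list(name = "etretinate", drugs = "etretinate",
           duration = list(dist = "exponential", median_months = 6),
           supp_prob = 0, staggered = FALSE),
      list(name = "secukinumab", drugs = "secukinumab",
           duration = list(dist = "exponential", median_months = 8),
           supp_prob = 0, staggered = FALSE)),
    init_probs = c(etretinate = 1),
    trans = list(etretinate = c(secukinumab = 1)),
    max_lines = 2L, transition_gap_days = c(0L, 0L), jitter_days = 0L)
  g <- generate_cohort(sc, seed = 31)
  cohort <- build_cohort(g$bundle)
  lots <- derive_lots_cohort(build_episodes(g$bundle), cohort)
  smp <- ttnt_samples(lots, cohort)
  first <- smp[smp$lot_number == 1L, ]
  med <- km_median_ci(km_fit(first$duration_days, first$event))$median
  expect_lt(abs(med - 6 * 30.4375) / (6 * 30.4375), 0.10)
})
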