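test_that("km_fit reproduces hand-computed product-limit values", {
  # {1,2,3} all events: S = 2/3, 1/3, 0
  f <- km_fit(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(f$time, c(1, 2, 3))
  expect_equal(f$surv, c(2/3, 1/3, 0))
  expect_equal(f$n_risk, c(3, 2, 1))

  # {2 event, 3 censored}: S(2) = 1/2 and stays there
  f2 <- km_fit(c(2, 3), c(TRUE, FALSE))
  expect_equal(f2$time, 2)
  expect_equal(f2$surv, 0.5)
  expect_equal(km_surv_at(f2, c(1, 2, 10)), c(1, 0.5, 0.5))

  # all censored: S identically 1
  f3 <- km_fit(c(5, 7), c(FALSE, FALSE))
  expect_equal(length(f3$time), 0L)
  expect_equal(km_surv_at(f3, c(1, 100)), c(1, 1))

  expect_error(km_fit(numeric(0), logical(0)), "no samples")
  expect_error(km_fit(c(0, 1), c(TRUE, TRUE)), "positive")
})

test_that("km median follows the smallest-time-at-half rule with log-log CI", {
  # S never reaches 0.5 -> median absent
  f <- km_fit(c(10, 20, 30), c(FALSE, FALSE, TRUE))  # S(30) = 0? n=1 at 30
  # with censoring first, S(30) = 0; use a case that truly stays above 0.5
  f <- km_fit(c(10, 20, 30, 40), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(tail(f$surv, 1), 0.75)
  expect_true(is.na(km_median_ci(f)$median))

  # {1,2,3,4} all events: S(2) = 0.5 exactly -> median 2
  f2 <- km_fit(1:4, rep(TRUE, 4))
  expect_equal(km_median_ci(f2)$median, 2)

  # degenerate single event at t = 5 -> median 5, CI (5, 5)
  f3 <- km_fit(5, TRUE)
  m3 <- km_median_ci(f3)
  expect_equal(m3$median, 5)
  expect_equal(m3$ci_lower, 5)
  expect_equal(m3$ci_upper, 5)
})

test_that("km_fit matches the reference implementation to 1e-10", {
  skip_if_not_installed("survival")
  set.seed(42)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    d <- sample(1:60, n, replace = TRUE)
    e <- runif(n) < 0.7
    if (!any(e)) e[1] <- TRUE
    fit <- km_fit(d, e)
    ss <- summary(survival::survfit(survival::Surv(d, e) ~ 1),
                  times = fit$time)
    expect_lt(max(abs(fit$surv - ss$surv)), 1e-10)
    expect_lt(max(abs(sqrt(fit$greenwood_var) - ss$std.err), na.rm = TRUE),
              1e-10)
  }
  # CI bounds agree with the log-log convention on a moderate sample
  set.seed(7)
  d <- rexp(80, 1 / 10); e <- runif(80) < 0.8
  med <- km_median_ci(km_fit(d, e))
  tab <- summary(survival::survfit(survival::Surv(d, e) ~ 1,
                                   conf.type = "log-log"))$table
  expect_equal(med$median, unname(tab["median"]))
  expect_equal(med$ci_lower, unname(tab["0.95LCL"]))
  expect_equal(med$ci_upper, unname(tab["0.95UCL"]))
})

test_that("km properties: conservation, duplication invariance, closed form", {
  set.seed(77)
  d <- sample(1:50, 30, replace = TRUE)
  e <- runif(30) < 0.6
  if (!any(e)) e[1] <- TRUE
  f <- km_fit(d, e)
  expect_equal(f$n_risk[1], sum(d >= f$time[1]))
  expect_equal(sum(f$n_event), sum(e))
  # duplicating every sample leaves S(t) unchanged
  f2 <- km_fit(c(d, d), c(e, e))
  expect_equal(f2$surv, f$surv)
  expect_equal(f2$time, f$time)
  # n = 2000 exponential event-only samples: median within 5% of ln2/rate
  set.seed(9)
  lam <- log(2) / 182.625
  m <- km_median_ci(km_fit(rexp(2000, lam), rep(TRUE, 2000)))$median
  expect_lt(abs(m - 182.625) / 182.625, 0.05)
})

test_that("TTNT samples censor the last line at end of follow-up", {
  cohort <- data.frame(patient_id = "A", included = TRUE, reason = "ok",
                       index_date = as.Date("2018-01-01"),
                       followup_end = as.Date("2018-01-01") + 200,
                       stringsAsFactors = FALSE)
  lots <- data.frame(
    patient_id = "A", lot_number = 1:2,
    start = as.Date("2018-01-01") + c(0, 90),
    end = as.Date("2018-01-01") + c(80, 150),
    specific_regimen = c("Etretinate", "Cyclosporin"),
    general_regimen = c("Etretinate", "Cyclosporin"),
    is_last = c(FALSE, TRUE), stringsAsFactors = FALSE)
  smp <- ttnt_samples(lots, cohort)
  expect_equal(smp$duration_days, c(90L, 110L))
  expect_equal(smp$event, c(TRUE, FALSE))

  # a single line yields one censored sample
  smp1 <- ttnt_samples(lots[1, ], cohort)
  expect_equal(nrow(smp1), 1L)
  expect_false(smp1$event)

  # duplicating a patient leaves KM medians unchanged
  lots_b <- lots; lots_b$patient_id <- "B"
  cohort_b <- cohort; cohort_b$patient_id <- "B"
  t1 <- ttnt_table(lots, cohort, "all_lines")
  t2 <- ttnt_table(rbind(lots, lots_b), rbind(cohort, cohort_b), "all_lines")
  expect_equal(t2$median_months, t1$median_months)
  expect_equal(t2$n, 2L * t1$n)
})

test_that("drug survival censors each patient's last episode", {
  cfg <- journey_config()
  ep <- data.frame(
    patient_id = "A", drug_code = "etretinate", episode_index = 1:2,
    start = as.Date("2018-01-01") + c(0, 200),
    end = as.Date("2018-01-01") + c(100, 400),
    duration_days = c(100L, 200L), n_prescriptions = c(3L, 6L),
    is_last = c(FALSE, TRUE), category2 = "Etretinate",
    stringsAsFactors = FALSE)
  fend <- c(A = as.Date("2019-06-01"))
  smp <- drug_survival_samples(ep, fend, config = cfg)
  expect_equal(smp$duration_days, c(100L, 200L))
  expect_equal(smp$event, c(TRUE, FALSE))

  # a single episode is censored under the default policy ...
  smp1 <- drug_survival_samples(ep[2, ], fend, config = cfg)
  expect_false(smp1$event)
  # ... but counts as an event under "near_followup" when it ends early
  cfg2 <- journey_config(censor_last_policy = "near_followup")
  smp2 <- drug_survival_samples(ep[2, ], fend, config = cfg2)
  expect_true(smp2$event)

  # cumulative 300 on-drug days: neither >1yr nor >2yr
  cohort <- data.frame(patient_id = "A", included = TRUE, reason = "ok",
                       index_date = as.Date("2018-01-01"),
                       followup_end = fend[["A"]], stringsAsFactors = FALSE)
  tab <- drug_survival_table(ep, cohort, config = cfg)
  expect_equal(tab$n_patients, 1L)
  expect_equal(tab$n_episodes, 2L)
  expect_equal(tab$n_gt1yr, 0L)
  # stretch one episode: cumulative 100 + 300 = 400 days -> >1yr only
  ep$end[2] <- ep$start[2] + 300
  ep$duration_days[2] <- 300L
  tab2 <- drug_survival_table(ep, cohort, config = cfg)
  expect_equal(tab2$n_gt1yr, 1L)
  expect_equal(tab2$n_gt2yr, 0L)
})
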