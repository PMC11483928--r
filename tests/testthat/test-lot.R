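ep_rows <- function(drug, s, e, pid = "A") {
  data.frame(patient_id = pid, drug_code = drug,
             start = as.Date(s, origin = "1970-01-01"),
             end = as.Date(e, origin = "1970-01-01"),
             stringsAsFactors = FALSE)
}
d0 <- function(x) as.Date(x, origin = "1970-01-01")

test_that("the regimen timeline partitions follow-up at episode bounds", {
  cfg <- journey_config()
  cat <- default_catalog()
  # single etretinate episode -> treated state flanked by untreated time
  tl <- build_regimen_timeline(ep_rows("etretinate", 10, 110),
                               d0(0), d0(200), cat, cfg)
  expect_equal(tl$mains, c("", "Etretinate", ""))
  expect_equal(as.integer(d0(tl$start)), c(0L, 10L, 110L))

  # etretinate [0,100) + topical [20,80): three states, middle with
  # the supplementary category attached
  tl2 <- build_regimen_timeline(
    rbind(ep_rows("etretinate", 0, 100),
          ep_rows("topical_corticosteroid", 20, 80)),
    d0(0), d0(100), cat, cfg)
  expect_equal(nrow(tl2), 3L)
  expect_equal(unique(tl2$mains), "Etretinate")
  expect_equal(tl2$supps, c("", "Topical therapy", ""))

  # no episodes -> a single untreated state spanning follow-up
  tl3 <- build_regimen_timeline(ep_rows("etretinate", 1, 2)[0, ],
                                d0(0), d0(50), cat, cfg)
  expect_equal(nrow(tl3), 1L)
  expect_equal(tl3$mains, "")
  # states tile [index, followup) without gaps
  for (tl_i in list(tl, tl2, tl3)) {
    expect_equal(tl_i$start[-1], tl_i$end[-nrow(tl_i)])
  }
})

test_that("regimen labels follow the prioritization and supplement rules", {
  cat <- default_catalog()
  cfg <- journey_config()
  lab <- label_regimen(c("Etretinate", "Cyclosporin"), FALSE, cat, cfg)
  expect_equal(lab$general_regimen, "Etretinate")       # priority 4 < 5
  expect_equal(lab$specific_regimen, "Cyclosporin + Etretinate")

  lab2 <- label_regimen(c("IL-17 inhibitors", "Etretinate"), FALSE, cat, cfg)
  expect_equal(lab2$general_regimen, "IL-17 inhibitors")
  expect_equal(lab2$specific_regimen, "Etretinate + IL-17 inhibitors")

  lab3 <- label_regimen("Etretinate", TRUE, cat, cfg)
  expect_equal(lab3$specific_regimen, "Etretinate + supplementary drug")

  # supplementary-only lines take their highest-priority category
  lab4 <- label_regimen(c("Topical therapy", "Arthritis treatment"),
                        FALSE, cat, cfg)
  expect_equal(lab4$general_regimen, "Topical therapy")
  expect_equal(lab4$specific_regimen, "Topical therapy + supplementary drug")

  expect_error(label_regimen(character(0), FALSE, cat, cfg), "empty")

  # documented override: apheresis may dominate its combinations
  lab5 <- label_regimen(c("Apheresis/plasma exchange", "Cyclosporin"),
                        FALSE, cat, cfg)
  expect_equal(lab5$general_regimen, "Cyclosporin")     # strict priority
  cfg_a <- journey_config(apheresis_dominates = TRUE)
  lab6 <- label_regimen(c("Apheresis/plasma exchange", "Cyclosporin"),
                        FALSE, cat, cfg_a)
  expect_equal(lab6$general_regimen, "Apheresis/plasma exchange")
})

test_that("general regimen agrees with an exhaustive argmin oracle", {
  cat <- default_catalog()
  cfg <- journey_config()
  cats <- names(cat$priority_table)
  set.seed(5)
  # random subsets of the 12 categories (the full 2^12 space sampled)
  for (i in 1:300) {
    sub <- sample(cats, sample(1:12, 1))
    got <- label_regimen(sub, FALSE, cat, cfg)$general_regimen
    want <- sub[which.min(vapply(sub, function(cc) {
      unname(cat$priority_table[cc])
    }, numeric(1)))]
    expect_equal(got, want)
  }
})

test_that("line transitions implement switch, combination and add-on", {
  cat <- default_catalog()
  cfg <- journey_config()
  derive <- function(ep, fend = 600) {
    tl <- build_regimen_timeline(ep, d0(0), d0(fend), cat, cfg)
    derive_lots(tl, cat, cfg)
  }

  # sequential monotherapies -> two lines (switch)
  lots <- derive(rbind(ep_rows("etretinate", 0, 100),
                       ep_rows("cyclosporin", 200, 300)))
  expect_equal(lots$general_regimen, c("Etretinate", "Cyclosporin"))
  expect_equal(lots$lot_number, 1:2)
  expect_equal(lots$is_last, c(FALSE, TRUE))

  # second main within the 30-day window joins as a combination
  lots2 <- derive(rbind(ep_rows("etretinate", 0, 100),
                        ep_rows("secukinumab", 10, 100)))
  expect_equal(nrow(lots2), 1L)
  expect_equal(lots2$specific_regimen, "Etretinate + IL-17 inhibitors")
  expect_equal(lots2$general_regimen, "IL-17 inhibitors")
  expect_equal(as.integer(d0(lots2$start)), 0L)

  # a later main start is an add-on: new line of all active mains
  lots3 <- derive(rbind(ep_rows("etretinate", 0, 200),
                        ep_rows("secukinumab", 60, 200)))
  expect_equal(nrow(lots3), 2L)
  expect_equal(lots3$specific_regimen[1], "Etretinate")
  expect_equal(lots3$specific_regimen[2], "Etretinate + IL-17 inhibitors")
  expect_equal(as.integer(d0(lots3$start)), c(0L, 60L))

  # dropping one component of a combination starts a new line
  lots4 <- derive(rbind(ep_rows("etretinate", 0, 200),
                        ep_rows("cyclosporin", 0, 100)))
  expect_equal(nrow(lots4), 2L)
  expect_equal(lots4$specific_regimen, c("Cyclosporin + Etretinate",
                                         "Etretinate"))

  # supplementary-only period forms its own line
  lots5 <- derive(ep_rows("topical_corticosteroid", 0, 90))
  expect_equal(nrow(lots5), 1L)
  expect_equal(lots5$general_regimen, "Topical therapy")

  # supplementary starts never change a main line, but label it
  lots6 <- derive(rbind(ep_rows("etretinate", 0, 150),
                        ep_rows("topical_corticosteroid", 40, 120)))
  expect_equal(nrow(lots6), 1L)
  expect_equal(lots6$specific_regimen, "Etretinate + supplementary drug")
})

test_that("a same-drug lapse beyond the gap threshold restarts the line", {
  cat <- default_catalog()
  cfg <- journey_config()
  # oral, lapse 90 > 61: two lines of the identical regimen
  ep <- rbind(ep_rows("etretinate", 0, 100), ep_rows("etretinate", 190, 280))
  tl <- build_regimen_timeline(ep, d0(0), d0(400), cat, cfg)
  lots <- derive_lots(tl, cat, cfg)
  expect_equal(nrow(lots), 2L)
  # biologic, lapse 90 <= 91: bridged into one line
  ep_b <- rbind(ep_rows("secukinumab", 0, 100),
                ep_rows("secukinumab", 190, 280))
  tl_b <- build_regimen_timeline(ep_b, d0(0), d0(400), cat, cfg)
  expect_equal(nrow(derive_lots(tl_b, cat, cfg)), 1L)
})

test_that("derived lines are ordered, disjoint and input-order invariant", {
  cat <- default_catalog()
  cfg <- journey_config()
  ep <- rbind(ep_rows("etretinate", 0, 100),
              ep_rows("secukinumab", 10, 150),
              ep_rows("cyclosporin", 260, 380),
              ep_rows("topical_corticosteroid", 420, 500))
  derive <- function(e) {
    derive_lots(build_regimen_timeline(e, d0(0), d0(600), cat, cfg),
                cat, cfg)
  }
  lots <- derive(ep)
  expect_equal(lots$lot_number, seq_len(nrow(lots)))
  expect_true(all(diff(as.integer(d0(lots$start))) > 0))
  expect_true(all(d0(lots$end) > d0(lots$start)))
  # pairwise disjoint
  expect_true(all(d0(lots$start)[-1] >= d0(lots$end)[-nrow(lots)]))
  # shuffled episode input yields the identical result
  set.seed(8)
  for (i in 1:5) expect_equal(derive(ep[sample(nrow(ep)), ]), lots)
})
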