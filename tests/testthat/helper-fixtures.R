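# shared fixtures and independent oracles, built in code

# a tiny consistent bundle: 3 patients, 7 prescriptions
make_fixture_bundle <- function() {
  patients <- data.frame(
    patient_id = c("A", "B", "C"),
    sex = c("female", "male", "female"),
    birth_year = c(1960L, 1975L, 1950L),
    death_date = as.Date(c(NA, NA, "2019-06-01")),
    stringsAsFactors = FALSE)
  diagnoses <- data.frame(
    patient_id = c("A", "A", "A", "B", "B", "C", "C", "C"),
    code = c("L40.1", "L40.1", "L40.0", "L40.1", "L40.1", "L40.1", "L40.1",
             "I21.0"),
    date = as.Date(c("2016-03-01", "2016-04-01", "2016-05-01", "2017-01-10",
                     "2017-02-10", "2018-02-01", "2018-03-01", "2017-06-01")),
    confirmed = TRUE, stringsAsFactors = FALSE)
  prescriptions <- data.frame(
    patient_id = c("A", "A", "A", "B", "B", "C", "C"),
    drug_code = c("etretinate", "etretinate", "secukinumab", "cyclosporin",
                  "cyclosporin", "etretinate", "topical_corticosteroid"),
    date = as.Date(c("2016-03-05", "2016-04-04", "2016-08-20", "2017-01-15",
                     "2017-02-14", "2018-02-05", "2018-02-05")),
    days_supply = c(30L, 30L, NA, 30L, 30L, 30L, 30L),
    stringsAsFactors = FALSE)
  claims_bundle(patients, diagnoses, prescriptions,
                c("2016-01-01", "2021-08-31"))
}

# brute-force episode merger: transitive closure of the pairwise
# "within gap" relation, independent of the sweep-line implementation
brute_force_merge <- function(s, e, gap) {
  n <- length(s)
  if (n == 0) return(cbind(s = integer(0), e = integer(0)))
  # adjacency: i ~ j when neither gap exceeds the threshold
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    lapse <- max(s[i] - e[j], s[j] - e[i])
    if (lapse <= gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- t(vapply(unique(comp), function(cc) {
    c(min(s[comp == cc]), max(e[comp == cc]))
  }, integer(2)))
  out <- out[order(out[, 1]), , drop = FALSE]
  colnames(out) <- c("s", "e")
  out
}

# random interval sets for the episode property tests
random_intervals <- function(n_max = 12L) {
  n <- sample.int(n_max, 1L)
  s <- sort(sample.int(400L, n, replace = TRUE))
  len <- sample.int(60L, n, replace = TRUE)
  list(s = as.integer(s), e = as.integer(s + len))
}

intervals_df <- function(s, e, pid = "X", drug = "etretinate") {
  data.frame(patient_id = rep(pid, length(s)),
             drug_code = rep(drug, length(s)),
             start = as.Date(s, origin = "1970-01-01"),
             end = as.Date(e, origin = "1970-01-01"),
             stringsAsFactors = FALSE)
}

# compare derived vs ground-truth line tables
expect_lots_equal <- function(derived, truth) {
  cols <- c("patient_id", "lot_number", "start", "end",
            "specific_regimen", "general_regimen", "is_last")
  d <- derived[, cols]
  t <- truth[, cols]
  rownames(d) <- rownames(t) <- NULL
  expect_equal(d, t)
}
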