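test_that("published age-band arithmetic reproduces from counts with the known-age denominator", {
  counts <- c(52, 235, 554, 2143, 4075, 2459, 2030)
  expect_equal(pct_of(counts[5], sum(counts)), 35.3)
  expect_equal(pct_of(counts, sum(counts))[1:6],
               c(0.5, 2.0, 4.8, 18.6, 35.3, 21.3))
})

test_that("an all-serious all-fatal cohort reports 100 percent for both", {
  rs <- as_report_set(tibble::tibble(
    report_id = c("r1", "r2"),
    drug_codes = c("D", "D"),
    reaction_terms = c("tin;aki", "tin"),
    serious = c("true", "true"),
    fatal = c("true", "true")
  ))
  s <- summarize_cohort(rs, case_terms = "tin")
  expect_equal(s$seriousness$pct, c(100, 100))
  # the case-defining term is excluded from co-reported terms
  expect_equal(s$coreported$term, "aki")
})

test_that("cohort summary equals brute-force tallies on a synthetic cohort", {
  sim <- generate_reports(small_config(n = 1000, seed = 63))
  cases <- select_cases(sim$reports, "E01")
  s <- summarize_cohort(cases, case_terms = "E01", top_k_countries = 5,
                        top_k_terms = 10)
  n <- nrow(cases)
  # age: plain tally per band
  for (band in age_bands()) {
    expect_equal(s$age$n[s$age$level == band],
                 sum(cases$age_group == band))
  }
  expect_equal(s$age$denominator[1], sum(cases$age_group != "unknown"))
  # seriousness and fatality over all reports
  expect_equal(s$seriousness$n, c(sum(cases$serious == "true"),
                                  sum(cases$fatal == "true")))
  # co-reported terms: report-level tally excluding the index term
  for (i in seq_len(nrow(s$coreported))) {
    term <- s$coreported$term[i]
    expect_equal(s$coreported$n[i],
                 sum(vapply(cases$reaction_terms,
                            function(v) term %in% v, logical(1))))
  }
  expect_false("E01" %in% s$coreported$term)
  # outcome percentages over known outcomes
  known <- sum(cases$outcome != "unknown")
  expect_equal(s$outcome$denominator[1:3], rep(known, 3))
  # every pct re-derives from its count and declared denominator
  long <- tidy(s)
  has_pct <- !is.na(long$pct)
  expect_equal(long$pct[has_pct],
               pct_of(long$n[has_pct], long$denominator[has_pct]))
})

test_that("cohort summaries are invariant to report order", {
  sim <- generate_reports(small_config(n = 300, seed = 71))
  cases <- select_cases(sim$reports, "E01")
  shuffled <- withr::with_seed(3, dplyr::slice_sample(cases, prop = 1))
  s1 <- tidy(summarize_cohort(cases, "E01"))
  s2 <- tidy(summarize_cohort(shuffled, "E01"))
  expect_equal(s1, s2)
})

test_that("time-to-onset quantiles use linear interpolation over known values", {
  one <- as_report_set(tibble::tibble(
    report_id = "r1", drug_codes = "D", reaction_terms = "E",
    time_to_onset_days = 10
  ))
  expect_equal(unlist(time_to_onset_summary(one)[, c("median", "q1", "q3")]),
               c(median = 10, q1 = 10, q3 = 10))
  five <- as_report_set(tibble::tibble(
    report_id = sprintf("r%d", 1:5), drug_codes = "D", reaction_terms = "E",
    time_to_onset_days = c(1, 2, 3, 4, 5)
  ))
  expect_equal(unlist(time_to_onset_summary(five)[, c("median", "q1", "q3")]),
               c(median = 3, q1 = 2, q3 = 4))
  # linear-interpolation oracle computed by hand: q_p at h = (n-1)p + 1
  manual_q <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  sim <- generate_reports(small_config(n = 500, seed = 83))
  tto <- sim$reports$time_to_onset_days
  known <- tto[!is.na(tto)]
  got <- time_to_onset_summary(sim$reports)
  expect_equal(got$median, manual_q(known, 0.5), tolerance = 1e-9)
  expect_equal(got$q1, manual_q(known, 0.25), tolerance = 1e-9)
  expect_equal(got$q3, manual_q(known, 0.75), tolerance = 1e-9)
  expect_equal(got$n_known, length(known))
  # no known values: not estimable
  none <- one
  none$time_to_onset_days <- NA_integer_
  expect_true(is.na(time_to_onset_summary(none)$median))
})

test_that("drug report shares count at report level and bound their classes", {
  dict <- tibble::tibble(
    drug_code = c("X", "Y", "Z"),
    display_name = c("x", "y", "z"),
    atc_path = list(c("classA", "x"), c("classA", "y"), c("classB", "z"))
  )
  db <- as_report_set(tibble::tibble(
    report_id = sprintf("r%d", 1:4),
    drug_codes = c("X;Y", "X", "Y", "Z"),
    reaction_terms = "E"
  ))
  subs <- drug_report_shares(db, dict)
  expect_equal(subs$n[subs$label == "x"], 2)
  cls <- drug_report_shares(db, dict, level = 1)
  a_share <- cls$n[cls$label == "classA"]
  expect_equal(a_share, 3) # union of {r1,r2} and {r1,r3}
  expect_gte(a_share, max(subs$n[subs$label %in% c("x", "y")]))
  expect_lte(a_share, sum(subs$n[subs$label %in% c("x", "y")]))
  # brute-force union oracle on a synthetic set
  sim <- generate_reports(small_config(n = 400, seed = 91))
  got <- drug_report_shares(sim$reports)
  for (i in seq_len(nrow(got))) {
    expect_equal(got$n[i],
                 sum(vapply(sim$reports$drug_codes,
                            function(v) got$label[i] %in% v, logical(1))))
  }
  expect_equal(got$pct, pct_of(got$n, nrow(sim$reports)))
})

test_that("cohort summaries export to delimited and JSON forms", {
  sim <- generate_reports(small_config(n = 200, seed = 15))
  cases <- select_cases(sim$reports, "E01")
  s <- summarize_cohort(cases, "E01")
  path <- withr::local_tempfile(fileext = ".csv")
  jpath <- withr::local_tempfile(fileext = ".json")
  write_cohort_summary(s, path, json_path = jpath)
  flat <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(flat), c("characteristic", "value"))
  expect_equal(flat$value[flat$characteristic == "total: reports"],
               as.character(nrow(cases)))
  j <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_true(all(c("section", "label", "n", "denominator") %in% names(j)))
})
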