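test_that("degenerate certainty config yields the forced drug-event pair", {
  cfg <- sim_config(
    n_reports = 10,
    drugs = tibble::tibble(drug_code = "D1", prob = 1),
    events = tibble::tibble(reaction_term = "E1", prob = 1),
    seed = 5
  )
  sim <- generate_reports(cfg)
  expect_equal(nrow(sim$reports), 10)
  expect_true(all(vapply(sim$reports$drug_codes, identical, logical(1), "D1")))
  expect_true(all(vapply(sim$reports$reaction_terms, identical, logical(1),
                         "E1")))
})

test_that("impossible configs fail explicitly at the resampling cap", {
  cfg <- sim_config(
    n_reports = 5,
    drugs = tibble::tibble(drug_code = "D1", prob = 0),
    events = tibble::tibble(reaction_term = "E1", prob = 1),
    seed = 5
  )
  expect_error(generate_reports(cfg, max_tries = 10), "degenerate")
})

test_that("identical configs generate byte-identical line listings", {
  cfg <- small_config(n = 300, seed = 42)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_line_listing(generate_reports(cfg)$reports, p1)
  write_line_listing(generate_reports(cfg)$reports, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("config validation rejects bad probabilities and orphan signals", {
  expect_error(sim_config(10, tibble::tibble(drug_code = "D", prob = 1.2),
                          tibble::tibble(reaction_term = "E", prob = 0.5)),
               "probabilities")
  expect_error(sim_config(10, tibble::tibble(drug_code = "D", prob = 0.5),
                          tibble::tibble(reaction_term = "E", prob = 0.5),
                          signals = tibble::tibble(drug_code = "ZZ",
                                                   reaction_term = "E",
                                                   rate = 2)),
               "declared")
  expect_error(sim_config(10, tibble::tibble(drug_code = "D", prob = 0.5),
                          tibble::tibble(reaction_term = "E", prob = 0.5),
                          age_probs = c("18-44y" = 0.7)),
               "sum to 1")
})

test_that("ground truth tabulates configured rates, with implied rate-1 pairs", {
  cfg <- small_config()
  sim <- generate_reports(cfg)
  tr <- summarize_truth(sim)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$rate, 5)
  full <- summarize_truth(cfg, implied = TRUE)
  expect_equal(nrow(full), nrow(cfg$drugs) * nrow(cfg$events))
  expect_equal(sum(full$rate != 1), 1)
  # no signals configured: all implied rates are 1
  cfg0 <- null_coverage_config(n = 100)
  expect_true(all(summarize_truth(cfg0, implied = TRUE)$rate == 1))
})

test_that("fired signal records match the reports carrying the pair", {
  sim <- generate_reports(small_config(n = 500, seed = 13))
  carried <- sim$reports$report_id[
    vapply(seq_len(nrow(sim$reports)), function(i) {
      "D01" %in% sim$reports$drug_codes[[i]] &&
        "E05" %in% sim$reports$reaction_terms[[i]]
    }, logical(1))]
  expect_setequal(sim$fired$report_id, carried)
})

test_that("conditional event frequencies are calibrated to baseline x rate", {
  # all-null config: every P(event | drug) within 3 binomial SEs of baseline
  sim <- cached("pair_calib", generate_reports(pair_calibration_config()))
  cfg <- sim$config
  for (d in cfg$drugs$drug_code) {
    for (j in seq_len(nrow(cfg$events))) {
      est <- empirical_cond_prob(sim$reports, d, cfg$events$reaction_term[j])
      p <- cfg$events$prob[j]
      se <- sqrt(p * (1 - p) / est["m"])
      expect_lt(abs(est["p"] - p), 3 * se)
    }
  }
  # one rate-10 signal on a rare event lands near 10 x baseline
  rec <- cached("recovery", generate_reports(recovery_config()))
  est <- empirical_cond_prob(rec$reports, "S01", "R01")
  se <- sqrt(0.05 * 0.95 / est["m"])
  expect_lt(abs(est["p"] - 0.05), 3 * se)
})

test_that("drug report shares are calibrated to the configured marginals", {
  sim <- cached("marginal_calib", generate_reports(marginal_calibration_config()))
  cfg <- sim$config
  n <- nrow(sim$reports)
  for (i in seq_len(nrow(cfg$drugs))) {
    share <- mean(vapply(sim$reports$drug_codes,
                         function(v) cfg$drugs$drug_code[i] %in% v,
                         logical(1)))
    p <- cfg$drugs$prob[i]
    expect_lt(abs(share - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("time-to-onset distribution reproduces the published median band", {
  sim <- cached("default10k",
                generate_reports(default_sim_config(n_reports = 10000)))
  tto <- time_to_onset_summary(sim$reports)
  expect_gte(tto$median, 15)
  expect_lte(tto$median, 26)
  expect_gt(tto$n_known, 5000)
})

test_that("ROR recovers the injected relative reporting rate (rare-event odds ~ risk)", {
  rec <- cached("recovery", generate_reports(recovery_config()))
  sig <- rec$config$signals
  rors <- vapply(seq_len(nrow(sig)), function(i) {
    t <- contingency_table(rec$reports, sig$reaction_term[i],
                           sig$drug_code[i])
    ror_ci(t$a, t$b, t$c, t$d)$ror
  }, numeric(1))
  expect_lt(abs(mean(rors) - 10) / 10, 0.10)
})

test_that("sim configs round-trip through YAML", {
  cfg <- small_config(n = 25, seed = 77)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$drugs, cfg$drugs)
  expect_equal(back$signals, cfg$signals)
  expect_equal(back$age_probs, cfg$age_probs)
  expect_equal(back$seed, cfg$seed)
  # and the round-tripped config generates the identical database
  expect_equal(generate_reports(back)$reports, generate_reports(cfg)$reports,
               ignore_attr = TRUE)
})
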