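test_that("ROR point estimate and Woolf CI reproduce textbook values", {
  # balanced table: ROR 1, CI symmetric about 1 in log space
  t0 <- ror_ci(10, 10, 10, 10)
  expect_equal(t0$ror, 1)
  expect_equal(log(t0$ror_high), -log(t0$ror_low))
  # worked example frozen from the Woolf formula:
  # ror = 30*900/(70*100); log-SE = sqrt(1/30+1/70+1/100+1/900)
  t1 <- ror_ci(30, 70, 100, 900)
  expect_equal(t1$ror, 27000 / 7000, tolerance = 1e-12)
  expect_equal(t1$ror_low, 2.39872, tolerance = 1e-4)
  expect_equal(t1$ror_high, 6.20228, tolerance = 1e-4)
  expect_false(t1$corrected)
})

test_that("Woolf CI agrees with an independent logistic-regression route", {
  cells <- list(c(30, 70, 100, 900), c(12, 40, 55, 400), c(5, 20, 11, 77))
  for (x in cells) {
    df <- data.frame(
      case = c(1, 0, 1, 0),
      exposed = c(1, 1, 0, 0),
      w = x
    )
    fit <- stats::glm(case ~ exposed, family = stats::binomial(),
                      data = df, weights = w)
    est <- exp(stats::coef(fit)[["exposed"]])
    ci <- exp(stats::confint.default(fit)["exposed", ])
    ours <- ror_ci(x[1], x[2], x[3], x[4])
    # IRLS converges to ~1e-6 relative precision
    expect_equal(ours$ror, est, tolerance = 1e-4)
    expect_equal(ours$ror_low, unname(ci[1]), tolerance = 1e-4)
    expect_equal(ours$ror_high, unname(ci[2]), tolerance = 1e-4)
  }
})

test_that("zero cells trigger the Haldane-Anscombe correction; empty margins are not estimable", {
  t <- ror_ci(7, 0, 13, 80)
  expect_true(t$corrected)
  expect_equal(t$ror, (7.5 * 80.5) / (0.5 * 13.5), tolerance = 1e-12)
  ne <- ror_ci(0, 0, 50, 950)
  expect_false(ne$estimable)
  expect_true(is.na(ne$ror))
  ne2 <- ror_ci(50, 950, 0, 0)
  expect_false(ne2$estimable)
})

test_that("ROR is scale invariant while its CI narrows", {
  t1 <- ror_ci(30, 70, 100, 900)
  t10 <- ror_ci(300, 700, 1000, 9000)
  expect_equal(t10$ror, t1$ror, tolerance = 1e-12)
  expect_lt(t10$ror_high / t10$ror_low, t1$ror_high / t1$ror_low)
})

test_that("IC is the shrunk log2 observed-to-expected", {
  # observed equals expected: IC exactly 0, lower bound negative
  ic0 <- information_component(4, 4)
  expect_equal(ic0$ic, 0)
  expect_lt(ic0$ic025, 0)
  expect_lt(ic0$ic025, ic0$ic)
  # frozen example: log2(30.5/3.5)
  ic1 <- information_component(30, 3)
  expect_equal(ic1$ic, log2(30.5 / 3.5), tolerance = 1e-12)
  expect_equal(ic1$ic, 3.1234, tolerance = 1e-4)
})

test_that("gamma IC025 matches a Monte-Carlo quantile oracle", {
  grid <- expand.grid(a = c(1, 5, 30, 500), e = c(0.1, 1, 10, 100))
  withr::with_seed(271828, {
    for (i in seq_len(nrow(grid))) {
      a <- grid$a[i]; e <- grid$e[i]
      mc <- log2(stats::quantile(stats::rgamma(1e6, shape = a + 0.5,
                                               rate = e + 0.5),
                                 0.025, names = FALSE))
      got <- information_component(a, e)$ic025
      expect_lt(abs(got - mc), 0.02)
    }
  })
})

test_that("IC shrinks toward zero and the credibility gap vanishes asymptotically", {
  # fixed ratio a/e = 4: ic < log2(4), increasing in a
  a <- c(2, 8, 32, 128)
  ic <- information_component(a, a / 4)$ic
  expect_true(all(diff(ic) > 0))
  expect_true(all(ic < log2(4)))
  # gap ic - ic025 shrinks monotonically as counts grow
  big <- information_component(c(1e2, 1e4, 1e6), c(1e2, 1e4, 1e6) / 4)
  gaps <- big$ic - big$ic025
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.01)
  expect_equal(big$ic[3], log2(4), tolerance = 1e-3)
})

test_that("legacy BCPNN IC approaches the gamma formulation for large counts", {
  n <- 1e6; n_exposed <- 5e4; n_cases <- 2e4
  a <- 3000
  e <- n_exposed * n_cases / n
  g <- information_component(a, e)
  b <- information_component(a, e, method = "bcpnn", n = n,
                             n_exposed = n_exposed, n_cases = n_cases)
  expect_equal(b$ic, g$ic, tolerance = 0.02)
  expect_equal(b$ic025, g$ic025, tolerance = 0.05)
  expect_lt(b$ic025, b$ic)
})

test_that("expected counts follow the independence margins", {
  expect_equal(expected_count(30, 70, 100, 900), 100 * 130 / 1100)
  # in-sample independence: e equals a
  expect_equal(expected_count(10, 90, 90, 810), 10)
})

test_that("signal criteria keep exactly the qualifying results", {
  withr::with_seed(8, {
    res <- tibble::tibble(
      label = sprintf("drug%03d", 1:100),
      n = rpois(100, 40),
      ic025 = rnorm(100, 0, 1)
    )
  })
  kept <- apply_signal_criteria(res, min_reports = 30, ic_threshold = 0)
  oracle <- res[res$ic025 > 0 & res$n >= 30, c("label", "n", "ic025")]
  expect_equal(kept$label, oracle$label)
  expect_true(all(kept$is_signal))
  # boundary rules: n = 29 excluded despite high IC; negative IC025 excluded
  edge <- tibble::tibble(label = c("x", "y"), n = c(29, 500),
                         ic025 = c(2, -0.1))
  expect_equal(nrow(apply_signal_criteria(edge)), 0)
  flagged <- apply_signal_criteria(edge, filter = FALSE)
  expect_equal(flagged$is_signal, c(FALSE, FALSE))
})

test_that("ranking is a stable descending sort with alphabetical ties", {
  withr::with_seed(9, {
    res <- tibble::tibble(
      label = sample(sprintf("drug%02d", 1:50)),
      n = sample(c(10, 50, 100), 50, replace = TRUE),
      ror = runif(50, 0.5, 20)
    )
  })
  byn <- rank_results(res, by = "n_reports")
  oracle <- res[order(-res$n, res$label), ]
  expect_equal(byn$label, oracle$label)
  byr <- rank_results(res, by = "ror")
  expect_equal(byr$label, res$label[order(-res$ror, res$label)])
  # explicit tie: equal key falls back to alphabetical order
  tie <- tibble::tibble(label = c("zeta", "alpha"), n = c(100, 100),
                        ror = c(1, 2))
  expect_equal(rank_results(tie, by = "n_reports")$label,
               c("alpha", "zeta"))
})

test_that("dispro_stats assembles consistent per-drug results", {
  sim <- generate_reports(small_config(n = 800, seed = 55))
  tabs <- contingency_tables(sim$reports, "E05")
  res <- dispro_stats(tabs)
  expect_true(all(res$ic025 <= res$ic))
  ok <- res$estimable & res$a > 0 & res$b > 0 & res$c > 0 & res$d > 0
  expect_true(all(res$ror_low[ok] <= res$ror[ok] &
                    res$ror[ok] <= res$ror_high[ok]))
  expect_equal(res$is_signal, res$ic025 > 0 & res$n >= 30)
  expect_equal(res$pct_of_cases, pct_of(res$a, res$a + res$c))
})

test_that("the analysis pipeline flags the strong injected signal", {
  sim <- cached("default10k",
                generate_reports(default_sim_config(n_reports = 10000)))
  fit <- dispro_analysis(sim$reports, "tubulointerstitial_nephritis")
  res <- tidy(fit)
  expect_s3_class(res, "tbl_df")
  # D01 carries a rate-30 association on the case term
  expect_true(res$is_signal[res$label == "D01"])
  g <- glance(fit)
  expect_equal(g$n_cases,
               nrow(select_cases(sim$reports, "tubulointerstitial_nephritis")))
  expect_equal(g$n_signals, sum(res$is_signal))
  # ranking is by descending exposed-case count
  expect_true(all(diff(res$n) <= 0))
})
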