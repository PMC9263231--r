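# Shared simulation configurations and a cache for the heavier synthetic
# databases so several test files can reuse one generation run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# small, fully featured config exercising unknowns and missing onset times
small_config <- function(n = 50, seed = 101) {
  sim_config(
    n_reports = n,
    drugs = tibble::tibble(drug_code = sprintf("D%02d", 1:6),
                           prob = c(0.6, 0.5, 0.4, 0.3, 0.2, 0.1)),
    events = tibble::tibble(reaction_term = sprintf("E%02d", 1:5),
                            prob = c(0.8, 0.5, 0.3, 0.2, 0.1)),
    signals = tibble::tibble(drug_code = "D01", reaction_term = "E05",
                             rate = 5),
    age_probs = c("18-44y" = 0.3, "45-64y" = 0.4, "65-74y" = 0.3),
    age_missing = 0.2,
    sex_probs = c(male = 0.5, female = 0.5), sex_missing = 0.1,
    country_probs = c(US = 0.6, FR = 0.4), country_missing = 0.05,
    reporter_probs = c(physician = 0.7, consumer = 0.3),
    reporter_missing = 0.2,
    seriousness_prob = 0.6, fatality_prob_given_serious = 0.1,
    outcome_probs = c(recovered = 0.5, recovering_or_sequelae = 0.2,
                      not_recovered = 0.3),
    outcome_missing = 0.3,
    tto_log_mean = log(20), tto_log_sd = 1.5, tto_missing_prob = 0.25,
    seed = seed
  )
}

# null config for CI coverage: no injected associations, moderate cells
null_coverage_config <- function(n = 50000, seed = 4711) {
  sim_config(
    n_reports = n,
    drugs = tibble::tibble(
      drug_code = sprintf("D%02d", 1:15),
      prob = c(0.30, 0.30, 0.25, 0.25, 0.20, 0.20, 0.20, 0.15, 0.15,
               0.10, 0.10, 0.10, 0.05, 0.05, 0.05)
    ),
    events = tibble::tibble(
      reaction_term = sprintf("E%02d", 1:12),
      prob = c(0.50, 0.40, 0.30, 0.25, 0.20, 0.15, 0.10, 0.08, 0.06,
               0.05, 0.04, 0.03)
    ),
    seed = seed
  )
}

# parameter-recovery config: ten rate-10 signals, each on its own rare
# event (baseline 0.005), plus common background drugs/events so the
# at-least-one resampling rule almost never fires
recovery_config <- function(n = 200000, rate = 10, seed = 1905) {
  sig_drugs <- sprintf("S%02d", 1:10)
  sig_events <- sprintf("R%02d", 1:10)
  sim_config(
    n_reports = n,
    drugs = tibble::tibble(
      drug_code = c(sig_drugs, sprintf("B%02d", 1:6)),
      prob = c(rep(0.05, 10), 0.5, 0.4, 0.3, 0.3, 0.2, 0.2)
    ),
    events = tibble::tibble(
      reaction_term = c(sig_events, "bg1", "bg2", "bg3"),
      prob = c(rep(0.005, 10), 0.9, 0.7, 0.5)
    ),
    signals = tibble::tibble(drug_code = sig_drugs,
                             reaction_term = sig_events,
                             rate = rate),
    seed = seed
  )
}

# pairwise calibration config: few drugs (their own marginals are allowed
# to be conditioned by the >=1-drug rule, which leaves P(event | drug)
# untouched) and two very common background events so that empty-reaction
# resampling is negligible
pair_calibration_config <- function(n = 50000, seed = 3141) {
  sim_config(
    n_reports = n,
    drugs = tibble::tibble(drug_code = sprintf("D%02d", 1:5),
                           prob = c(0.5, 0.4, 0.3, 0.2, 0.1)),
    events = tibble::tibble(
      reaction_term = sprintf("E%02d", 1:8),
      prob = c(0.95, 0.90, 0.50, 0.30, 0.20, 0.10, 0.05, 0.02)
    ),
    seed = seed
  )
}

# marginal-share calibration config: enough common drugs that the
# >=1-drug resampling rule is essentially never triggered
marginal_calibration_config <- function(n = 50000, seed = 2718) {
  sim_config(
    n_reports = n,
    drugs = tibble::tibble(drug_code = sprintf("D%02d", 1:18),
                           prob = c(rep(0.4, 3), rep(0.3, 15))),
    events = tibble::tibble(reaction_term = c("bg1", "bg2", "E1"),
                            prob = c(0.9, 0.6, 0.1)),
    seed = seed
  )
}

# empirical P(event | drug) for one drug-event pair of a report set
empirical_cond_prob <- function(reports, drug, event) {
  exposed <- vapply(reports$drug_codes, function(v) drug %in% v, logical(1))
  hit <- vapply(reports$reaction_terms, function(v) event %in% v, logical(1))
  c(p = mean(hit[exposed]), m = sum(exposed))
}

# brute-force double-loop 2x2 oracle, deliberately naive
brute_force_table <- function(reports, case_terms, drug_codes) {
  a <- b <- c_ <- d <- 0L
  for (i in seq_len(nrow(reports))) {
    exposed <- any(reports$drug_codes[[i]] %in% drug_codes)
    case <- any(reports$reaction_terms[[i]] %in% case_terms)
    if (exposed && case) a <- a + 1L
    else if (exposed) b <- b + 1L
    else if (case) c_ <- c_ + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = c_, d = d)
}

# four-report toy database covering all exposure/case combinations
toy_db <- function() {
  as_report_set(tibble::tibble(
    report_id = c("r1", "r2", "r3", "r4"),
    drug_codes = c("D", "D", "X", "X"),
    reaction_terms = c("E", "other", "E", "other")
  ))
}
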