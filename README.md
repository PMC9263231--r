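# sradispro

Disproportionality analysis of spontaneous adverse-event reports in R.

Pharmacovigilance databases (FAERS, VigiBase and their national
counterparts) collect *individual case safety reports*: spontaneous
notifications that a patient on one or more drugs experienced one or more
suspected adverse reactions. Because these systems have no denominator of
exposed patients, drug–event associations are screened by
**disproportionality**: is an event reported with a drug more often than the
rest of the database would predict? `sradispro` implements that screening
pipeline end to end for analysts characterising a case series defined by a
reaction term (the motivating use case is drug-induced tubulointerstitial
nephritis, TIN), together with a fully parameterised synthetic
report-database generator so every estimator can be validated against known
ground truth.

Everything is tidyverse-native: report sets are tibbles (with list-columns
for the multi-valued drug and reaction fields), every step is a
pipe-friendly function, fitted analyses have `tidy()`/`glance()` methods and
`autoplot()` displays.

## The statistics

For each drug (or ATC-style drug class, pooled as the *union* of its
members' reports), the database is cross-classified into the 2×2 table

|              | case | non-case |
|--------------|------|----------|
| drug present | a    | b        |
| drug absent  | c    | d        |

* **Reporting odds ratio.** ROR = (a·d)/(b·c), with the Woolf (log-odds
  normal) 95 % CI `exp(log ROR ± z₀.₉₇₅ √(1/a + 1/b + 1/c + 1/d))`, and the
  Haldane–Anscombe +0.5 correction of all four cells when any cell is zero
  (flagged in the output).
* **Information component.** With E = (a+b)(a+c)/N the expected count under
  independence, IC = log₂((a + 0.5)/(E + 0.5)); its lower 95 % credibility
  bound IC025 is log₂ of the 2.5 % quantile of a Gamma(a + 0.5, rate E + 0.5)
  posterior (the WHO/UMC shrinkage formulation; the legacy BCPNN normal
  approximation is available via `ic_method = "bcpnn"`).
* **Signal criteria.** The classical screen IC025 > 0 with ≥ 30 case
  reports; results rank by case-report count or ROR with deterministic
  alphabetical tie-breaks.

Cohort descriptives (age bands, countries, reporters, seriousness,
fatality, outcomes, co-reported terms, time-to-onset quantiles) follow the
printed-table conventions: report-level counting, explicit `"unknown"`
categories, percentages over the declared denominator (known values for age
and outcome, all case reports elsewhere), one decimal, half away from zero.

## Worked example

```r
library(sradispro)

sim   <- generate_reports(default_sim_config(n_reports = 20000, seed = 11))
cases <- select_cases(sim$reports, "tubulointerstitial_nephritis")
fit   <- dispro_analysis(sim$reports, "tubulointerstitial_nephritis")
fit
#> Disproportionality analysis
#>   database: 20000 reports;  cases: 2998 (tubulointerstitial_nephritis)
#>   signals (IC025 > 0 , n >= 30 ): 5 of 40
#>  label     level    n pct_of_cases   ror ror_low ror_high  ic025 is_signal
#>    D01 substance 1780         59.4 4.491   4.143     4.87  0.928      TRUE
#>    D03 substance 1266         42.2 2.197   2.028     2.38  0.535      TRUE
#>    D05 substance  860         28.7 1.276   1.171     1.39  0.119      TRUE
#>    D02 substance  849         28.3 0.979   0.898     1.07 -0.117     FALSE
#>    D04 substance  771         25.7 0.992   0.907     1.08 -0.111     FALSE
#>    D06 substance  698         23.3 0.973   0.888     1.07 -0.134     FALSE
```

The generator injected six true associations on the case term (relative
reporting rates 30, 20, 10, 10, 5 and 3; `summarize_truth(sim)` lists
them). The three strongest — D01, D03, D05 — plus two weaker ones clear
the IC025 > 0, n ≥ 30 screen at this database size; rate-3 signals need a
larger database, which is exactly the shrinkage behaviour the IC is
designed for. The ROR estimates sit near the injected rates deflated by the
case term's 1 % baseline among comparator reports (e.g. D01: ROR ≈ 4.5
because the rate-30 boost saturates against the other injected signals in
the comparator).

```r
glance(summarize_cohort(cases, "tubulointerstitial_nephritis"))
#> # A tibble: 1 × 7
#>   n_total n_serious pct_serious n_fatal pct_fatal tto_median tto_n_known
#> 1    2998      2408        80.3     171       5.7         23        2144
```

The simulated cohort reproduces the study conditions it was calibrated to:
~80 % serious reports, ~6 % fatal, median onset ≈ 3 weeks.

`autoplot(fit)` draws IC025 against ROR with signals highlighted;
`plot_ror_forest(fit)` gives the ranked forest plot;
`plot_time_to_onset(cases)` the log-scale onset histogram.

Thin command-line wrappers over the same functions live in `inst/cli/`
(`simulate.R`, `dispro.R`) for shell pipelines.

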