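---
title: "Disproportionality screening of spontaneous reports: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sradispro)
```

## The problem

A spontaneous-reporting system collects individual case safety reports:
one notification per suspected adverse drug reaction episode, carrying one
or more drug codes, one or more reaction terms, partial demographics,
seriousness and outcome flags, and sometimes a time to onset. There is no
exposure denominator — we observe only *reports* — so drug–event
associations are screened by disproportionality: comparing how often an
event is reported with a drug against how often the rest of the database
would predict. The motivating application is a case series of
tubulointerstitial nephritis (TIN), a predominantly drug-induced
inflammatory kidney injury whose presumptive diagnosis leans heavily on
knowing which drugs are most suspect: proton pump inhibitors, several
antibiotic classes and NSAIDs dominate both the raw report counts and the
disproportionality rankings in large safety databases.

`sradispro` covers the full path: a tidy line-listing data model with
de-duplication, case selection, 2×2 contingency construction with
ATC-style class pooling, the ROR and IC statistics with their interval
estimates, cohort descriptives, and a synthetic report generator with
injected ground-truth associations for validating all of it.

## Counting rules

The report is the counting unit everywhere. A report mentioning a drug
twice, or mentioning two members of a pooled class, contributes exactly one
exposed report; a class table is therefore the table of the *union* of its
members' report-ID sets, never a cell-wise sum (`contingency_tables()`
asserts the shared margins `a + c = |cases|`, `a + b + c + d = |database|`
on every output). All drug mentions count as exposure regardless of the
reported role; the comparator is always the rest of the whole database.
Unknown is an explicit category rather than an absence, which keeps
known-value denominators auditable.

De-duplication keeps, among rows sharing a report ID, the row with the
fewest unknown fields (ties: first occurrence). Source systems perform
internal duplicate detection whose rules are not public; fewest-unknowns is
this package's own rule, chosen because a re-transmission that fills in
fields should supersede its stub, and it is deterministic.

## The estimators

**ROR.** For a table (a, b, c, d), `ror_ci()` returns
ROR = ad/bc with the Woolf interval
exp(log ROR ± z·√(1/a + 1/b + 1/c + 1/d)). A zero in any cell triggers the
Haldane–Anscombe correction (+0.5 to *all four* cells) and a `corrected`
flag; a drug present on no report or on every report is returned as
not-estimable rather than silently corrected. The interval is a screening
device: no multiplicity adjustment is applied, matching field practice of
reporting unadjusted 95 % CIs alongside an IC-based screen.

**IC.** With E = (a+b)(a+c)/N, `information_component()` returns the
shrinkage observed-to-expected IC = log₂((a+0.5)/(E+0.5)), and IC025 as
log₂ of the 2.5 % quantile of Gamma(shape a+0.5, rate E+0.5). The +0.5
terms shrink small-count pairs toward IC = 0, so every table is estimable
without continuity handling, and IC < log₂(a/E) whenever a > E. Different
historical formulations of the IC exist; this package defaults to the
gamma-quantile shrinkage form currently used for routine signal detection
at the WHO programme, and offers the legacy BCPNN normal approximation
(Dirichlet/Beta priors, `method = "bcpnn"`) for comparison with older
analyses. Published IC025 values computed on other databases (or with the
other formulation) should not be expected to reproduce exactly.

**Signal criteria.** The classical screen keeps pairs with IC025 > 0 and at
least 30 case reports; both thresholds are arguments. Ranking is a stable
descending sort with alphabetical tie-breaks, so rankings are reproducible.

## Descriptive conventions

Percentages follow printed-table arithmetic: one decimal, half away from
zero (`pct_of()`). Denominators are field-specific — a fact forced by the
arithmetic of published cohort tables, where age-band and outcome
percentages only re-derive over reports with *known* age/outcome while
seriousness, fatality, country, reporter, co-reported-term and drug shares
only re-derive over *all* case reports. Every section of a
`cohort_summary` therefore records its denominator explicitly, and the test
suite checks that each percentage re-derives from its count and declared
denominator. Time-to-onset quantiles use the linear-interpolation
definition (`stats::quantile` type 7); at cohort sizes of 10³–10⁴ any
mainstream quantile definition gives the same integer summaries.

`tin_reference_cohort()` rebuilds a 15,696-report TIN cohort from published
marginal tallies so that these conventions can be exercised against known
printed values. Two source quirks are handled explicitly: the published
reporter-qualification counts sum to more than the cohort (overlapping
categories), so the named categories keep their printed counts and
"unknown" absorbs the remainder; and the ≥75-year row's printed percentage
(17.8) does not re-derive from its count over the known-age denominator
(2030/11548 = 17.6 %), which we treat as a typo in the source — the
rebuilt cohort reports 17.6. Only the published *marginal* tallies are
reproduced; the joint distribution across fields (and the filler drug
codes covering the unnamed remainder of each class) is synthetic, and
labelled as such.

## The synthetic reporting system

`generate_reports()` simulates a database under a deliberately simple
generative model:

1. **Drugs.** Independent Bernoulli exposure per drug with configured
   marginal probabilities. Reports drawing zero drugs are redrawn (hard cap
   `max_tries`, then an explicit degenerate-configuration error).
2. **Reactions.** Given the report's drugs, each reaction term occurs with
   probability `baseline × rate`, capped at 1, where `rate` is the largest
   relative reporting rate among the report's drugs for that term (1 when
   no injected association applies). Zero-reaction reports are redrawn the
   same way.
3. **Everything else.** Age band, sex, country and reporter are categorical
   draws with explicit missingness probabilities; seriousness is Bernoulli;
   fatality is drawn only among serious reports (enforcing fatal ⇒
   serious); outcome is categorical; time to onset is log-normal, rounded
   to whole days, with a missingness probability.

One global seed drives a single stream; identical configurations produce
byte-identical line listings.

What the model deliberately omits: correlated co-prescription, syndrome
correlation between reaction terms, temporal reporting dynamics,
stimulated-reporting waves and masking. These change the margins of real
databases but not the estimators under test, which treat each drug–event
pair's 2×2 table marginally. Passing calibration tests on this generator
therefore validates the *estimators and counting rules*, not robustness to
those real-data phenomena.

A consequence of the ≥1-drug/≥1-reaction resampling rule is that very
sparse configurations condition the realised margins upward. The bundled
configurations are chosen so this conditioning is negligible against the
3-standard-error calibration bands: expected drugs per report around 4–6
(heavy polypharmacy, typical of the elderly populations in nephrotoxicity
reporting) and a few common background reaction terms (the most frequent
terms in real systems are generic ones such as "drug ineffective") keeping
the empty-draw probability well below 1 %.

### Study-calibrated defaults

`default_sim_config()` fixes the generator at the conditions of the TIN
case series: 40 drugs with geometrically decaying exposure (0.30 down to
~0.04), 25 reaction terms including a rare case-defining term
(`tubulointerstitial_nephritis`, baseline 1 %) carrying six injected
associations at rates 30–3; age-band, sex, country and reporter marginals
at the published proportions with their published missingness (26.4 % of
reports lack an age band, 47.6 % an outcome); 79.5 % serious, 7.8 %
fatality among serious; and a log-normal time to onset with median 20 days.
The log-scale SD 2.243 is the log-space moment match of the published
interquartile range (5–103 days about a median of 20): a two-parameter
log-normal cannot hit both printed quartiles exactly, so the fitted curve
has quartiles ≈ 4.4 and ≈ 91 days — right-skewed with a similar spread.
Time-to-onset missingness (30 %) is not published and was set once at a
typical completeness level for onset fields. These defaults are the study
conditions for all calibration work and are not tuned per analysis.

## Numerical and testing choices

* IC025 is validated against a 10⁶-draw Monte-Carlo quantile oracle on a
  16-point (a, E) grid spanning four orders of magnitude, at 0.02-bit
  agreement.
* Woolf CIs are cross-checked against an independent logistic-regression
  (Wald) route, and their null coverage is measured empirically across 180
  rate-1 pairs on a 50,000-report database — the acceptance band is the
  3-standard-error binomial band around 95 %.
* Parameter recovery uses ten injected rate-10 signals on rare
  (baseline 0.005) events at n = 200,000, each on its own event so the
  rest-of-database comparator stays at baseline; ROR then estimates the
  injected rate up to the odds-vs-risk gap (≈ +5 % at these baselines), and
  all ten must clear the signal screen.
* Problem sizes in the routine test suite (databases of 50–50,000 reports,
  one 200,000-report recovery run, 10⁶-draw oracles) were chosen to give
  those statistical checks comfortable power while keeping a full run in
  tens of seconds.
* Ranking ties break alphabetically; duplicate resolution ties break to
  first occurrence; both to keep every pipeline output order-deterministic.

## Known limitations

Screening, not inference: no multiplicity control, no causality
assessment, and crude (unstratified) tables only — confounding by age, sex
or country is untouched. Reaction terms and drug codes are opaque strings;
no licensed-dictionary (MedDRA/WHODrug) semantics, no E2B ingestion, and
no combination-product splitting (combination codes are distinct
substances, as in published rankings). ROR values computed on a synthetic
or partial database are not comparable to values computed against the full
margins of a production database: the comparator differs, which is also
why published drug-level RORs are not reproduction targets for this
package's synthetic runs.
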