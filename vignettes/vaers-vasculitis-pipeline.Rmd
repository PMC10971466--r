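---
title: "Methods: vasculitis adverse-event analysis on VAERS"
author: "vaersvasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vasculitis adverse-event analysis on VAERS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaersvasc)
```

## The problem

The U.S. Vaccine Adverse Event Reporting System (VAERS) is a passive
surveillance registry: anyone may file a report after vaccination, and each
yearly release ships as three comma-separated files joined on a report
identifier — per-report data (`VAERSDATA`), up to five MedDRA preferred
terms per symptom row with continuation rows for longer lists
(`VAERSSYMPTOMS`), and one row per administered vaccine (`VAERSVAX`).
This package implements a reusable pipeline for retrospective analysis of
the rare vasculitis adverse events — Kawasaki disease (KD), the
Multisystem Inflammatory Syndrome family (MIS, MIS-A, MIS-C),
Henoch–Schönlein purpura (HS), and vasculitis — in that stream: ingestion,
case flagging, normalized-frequency tabulation, inference against a
background incidence, and an expected-count model of reporting with a
Monte-Carlo layer.

Passive surveillance counts cannot estimate true incidence. The package's
central statistic is therefore the *normalized reporting frequency*: cases
per 100,000 reports-with-symptoms within a stratum (a vaccine code, or a
single-year age). Comparing this quantity *across* strata asks a weaker but
well-posed question: are the reporting rates exchangeable, as they should
be if cases merely reflect the background population rate?

## The reporting model

For adverse event $X$, a population of $P_{age}$ individuals per
single-year age $0..100$ observed over a collection horizon of $n$ days
produces an expected background report count

$$E_{bg} = \sum_{age=0}^{100} P_{age} \sum_{day=0}^{n} r_{day}\, b_{age},$$

where $b_{age}$ is the age-indexed per-person per-day background event
probability and $r_{day} \in [0,1]$ is a day-indexed reporting bias: the
probability that an event with onset $day$ days after vaccination is
reported at all, declining as onset moves away from the vaccination date.
A vaccine adds an age-indexed attributable excess $v_{age}$ inside the day
sum:

$$E_{vax} = \sum_{age=0}^{100} P_{age} \sum_{day=0}^{n} r_{day}\,(v_{age} + b_{age}).$$

`expected_events_background()` and `expected_events_vaccine()` evaluate
these sums exactly; the unit suite checks them against a literal
double-loop oracle at $10^{-12}$ relative tolerance. The model as stated
gives expectations only. For simulation we add a distributional layer:
Poisson per `(age, day)` cell with the cell's mean (the standard
rare-event approximation), with an exact per-person binomial mode for
small integer populations (`simulate_counts(method = "binomial")`). The
choice of distribution is this package's, made explicit because nothing in
the expectation model forces it.

`r_day` is a free vector; the synthetic default is geometric decay
$r_{day} = \rho^{day}$ with $\rho = 0.85$ over a 30-day horizon. That
shape is the simplest monotone decay consistent with declining reporting
probability, and 30 days is the span over which onset-day tabulations are
reported; both are parameters, not commitments.

## Case extraction

The six studied categories are flagged by matching MedDRA preferred terms:
`Kawasaki's disease` (the VAERS spelling, with apostrophe),
`Multisystem Inflammatory Syndrome` and its `... in adults` / `... in
children` variants, `Henoch-Schonlein purpura`, and `Vasculitis`, plus the
composite `KD, MIS, MIS-A, or MIS-C` (union semantics). A report is one
case per category no matter how many of its terms match.

Matching is **exact** (after case-folding, trimming, and whitespace
collapse) by default. This is a real decision: under substring matching,
`Vasculitis` would also capture `Cutaneous vasculitis`,
`Vasculitis gastrointestinal`, and dozens of other distinct preferred
terms, silently inflating counts. Exact matching on the listed preferred
terms is the conservative reading; `term_policy("substring")` is retained
as an explicit sensitivity switch, and the synthetic generator plants a
superstring decoy so tests exercise the difference.

## Tabulation conventions

Two integer conventions coexist in published VAERS vasculitis tabulations
and are kept explicit throughout:

* **round-to-nearest** (half away from zero) for the per-vaccine table;
* **truncation** for the per-age table.

Auditing the bundled published tables against their own (count,
denominator) pairs confirms both conventions cell-by-cell, with one
exception: the per-age table's age-29 cell ($10^5 \cdot 1/14700 = 6.80$)
prints 7, which truncation cannot produce (round-to-nearest can). The
bundled CSV keeps the printed value verbatim and the tests document the
cell as the single convention-inconsistent entry rather than smoothing it
over.

When a stratum has zero cases the frequency is reported as the upper bound
`"<k"` with $k = \lfloor 10^5 / \text{denominator} \rfloor$ — the largest
integer frequency a single case could not have exceeded. Age-band
summaries (`group_summary()`) expose a `zero_count_policy`: either exclude
zero-count ages or substitute the bound's integer, the latter matching how
published age-band means over bands containing zero-count ages are
computed.

The per-vaccine table pairs an **ages 0–5 denominator with an all-ages
case count** by default. This asymmetry is deliberate and prominent: it is
the only reading that reproduces the published per-vaccine rows, where the
denominator column is headed as early-childhood vaccinations while case
counts include adults. Both windows are independent parameters
(`denominator_ages`, `numerator_ages`), so a symmetric all-ages table is
one argument away. Ages bin as `floor(age_years)`; missing ages form an
`N.A.` bucket and are excluded from any explicit age window. A report
listing $k$ distinct vaccine codes contributes once to each of the $k$
rows — no fractional attribution, the only rule consistent with
integer-valued published rows.

## Inference

Each vaccine's case count is tested against a background incidence (default
20 per 100,000, with 9 as the usual sensitivity value for KD) by a
two-cell chi-squared goodness-of-fit: observed (cases, non-cases) versus
expected under $p_0 = \text{rate}/10^5$, $df = 1$, upper-tail p-value, no
continuity correction by default (switchable), with an exact binomial
alternative for small expected counts. The "per year" qualifier on
published background rates has no per-report analogue; it is ignored by
default (the comparison is per report, as the frequencies are), and a
`year_scale` factor exists for anyone who wants a calendar interpretation.
When an expected cell is below 1 the result carries an explicit
approximation caveat rather than failing.

The family of per-vaccine tests is controlled by Bonferroni:
`alpha / m` with `m` the number of retained strata. The unknown-vaccine
code `UNK` is excluded by default — a frequency for "unknown vaccine" tests
no vaccine — though the published 30-row family includes it, so the
reproduction script runs the screen without exclusions.

The cross-vaccine **homogeneity test** (`homogeneity_test()`) is the
operational form of the background-only hypothesis: Pearson's chi-squared
test of independence on the $K \times 2$ table of cases versus non-cases
per stratum, $df = K - 1$. Rejection means the normalized frequencies are
not exchangeable across vaccines — the observed per-vaccine spread cannot
be background variation alone.

## The simulation study

`hypothesis_power_curve()` quantifies that comparison. Strata draw Poisson
case counts from the expected-count model; stratum 1's attributable rate is
$v$ times the background, $v = 0$ being the null. The default study
conditions are 10 strata of $n = 5{,}000$ reports at a shared rate of
**350 per 100,000** — the median of the published per-vaccine normalized
frequencies, i.e. the middle of the regime the method is actually applied
in. At that rate each stratum expects ~17.5 cases, squarely inside the
range where the chi-squared approximation is textbook-accurate; a
20,000-replicate check estimates the test's true size at
$0.047 \pm 0.002$ against the nominal 0.05. (At the much rarer KD
background of 20 per 100,000 the expected count per stratum is 1; the
Pearson statistic remains usable but tail accuracy degrades, which is why
the calibration study is not run there.) The in-suite calibration test
uses 4,000 replicates so that the estimate's own Monte-Carlo error
(SE ≈ 0.003) is small against the acceptance band; power at a 10×
stratum under these conditions is indistinguishable from 1.

All randomness flows through a single integer seed; seeded routines save
and restore the caller's RNG state, so a fixed seed gives bit-identical
simulator output without side effects.

## The synthetic generator

`generate_vaers()` emits a triplet in the exact dialect the reader parses,
plus a JSON sidecar with the ground truth (per-report flags, per-vaccine
case counts and reports-with-symptoms denominators). The truth lives
*beside* the data files, never inside them, so a round-trip test cannot
cheat. Defaults emulate the early-childhood study conditions: several
vaccines at a 20/100,000 background with excess rates spanning the
observed range (tens to thousands per 100,000), uniform ages 0–5, geometric
onset decay ($\rho = 0.85$, truncated at day 30), ~8% missing ages, ~30%
missing onset days (the blank-onset share of published onset tables), 15%
co-administration, 2% of reports with no symptom row, and symptom counts
that exceed five terms often enough to force continuation rows.
`fixture_small()` is a hand-written 12-report triplet covering every
corner case at once (multi-vaccine report, continuation rows, duplicate
terms, missing fields, `UNK`, the superstring decoy).

What the generator does **not** emulate — free-text narratives, real
MedDRA coding drift across dictionary versions, demographic structure
beyond a uniform age draw, duplicate and follow-up reports — bounds what
passing tests show: the pipeline's arithmetic and bookkeeping are exact on
data with known truth, not that real VAERS data are clean.

## Numerical and degenerate-input choices

* Unparseable numeric cells become `NA`, never 0; ages outside [0, 120]
  and negative onset intervals become `NA`.
* Real exports are Windows-1252; files whose bytes are not valid UTF-8 are
  decoded as latin1.
* Duplicate report ids: within a file, first occurrence wins with a
  warning; across year files, first year wins with a logged count.
  Orphan symptom/vaccine rows are counted, not silently dropped.
* `homogeneity_test()` with an all-zero (or all-case) margin returns
  statistic 0, p = 1: identical strata carry no evidence, and erroring
  would break null simulations at very low rates.
* Half-away-from-zero rounding is implemented as
  `floor(x + 0.5)` for the non-negative frequencies here, deliberately not
  R's banker's `round()`.

## Problem sizes

The test suite runs the full pipeline on synthetic cohorts of 10,000
reports, model-vs-oracle checks on 100 random parameter sets, simulator
calibration on 10,000 replicates, and homogeneity calibration on 4,000
replicates; the reproduction script uses 1,000 replicates for the
calibration study. These sizes put Monte-Carlo standard errors well inside
the asserted tolerances while keeping a full run in the low minutes on one
core.

## Limitations

Everything here is about *reporting*, not incidence or causation: the
package quantifies whether reporting frequencies are exchangeable across
vaccines under an explicit reporting-bias model, and reproduces published
tabulation arithmetic. The model's `r_day`, `b_age`, `v_age` are not
estimable from counts alone and are never fitted — they are inputs for
expectation and simulation. The published per-vaccine case counts
themselves are not reproducible without the full VAERS download; what is
reproducible from printed integers alone (frequencies, thresholds, band
summaries, convention audits) is exactly what the tests and the
reproduction script compute.
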