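---
title: "Disproportionality signal mining with pvmine: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal mining with pvmine: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvmine)
library(data.table)
```

## The problem

Spontaneous reporting systems collect suspected adverse drug events without
an exposure denominator, so the only available signal-detection strategy is
disproportionality: asking whether a drug–event pair is reported more often
than the rest of the database would predict. `pvmine` implements that
workflow for FAERS-style quarterly ASCII extracts, specialized to the common
single-drug study design: pool quarters, deduplicate cases, select the
drug's reports as the cohort and everything else as the background, compute
per-event statistics, and screen the strong signals against the product
label.

This vignette documents the model and the design decisions; the README
shows the surface-level workflow.

## Data model and ingestion

FAERS distributes six "$"-delimited tables per quarter: DEMO (one row per
report version), DRUG, REAC, OUTC, THER and INDI (children keyed by
PRIMARYID). The dialect has no quoting, legacy quarters contain non-UTF-8
bytes, and malformed lines occur. The reader therefore decodes as Latin-1
with replacement, right-pads short lines with blanks, truncates lines whose
embedded "$" pushes them past the header arity (counting the overflow), and
treats only a missing mandatory column as fatal. Pre-2012 legacy headers are
handled by a small alias map (`ISR` → `primaryid`, `CASE` → `caseid`,
`GNDR_COD` → `sex`).

Dates are kept as raw strings plus a parsed form with an explicit precision
flag (day / month / year / invalid). A partial date is never silently
promoted to day precision: the time-to-onset computation requires day
precision on both of its operands and bins anything else as
missing/invalid, which is what makes the missing-data accounting honest.

Ages are normalized to years with the FAERS unit codes (DEC ×10, YR ×1,
MON ÷12, WK ÷52.14, DY ÷365.25, HR ÷8766); an unrecognized unit yields a
missing age rather than a guess. A blank unit is read as years, the
dominant convention in real extracts.

## Deduplication

Follow-up versions of a case arrive across quarters under one CASEID with
different PRIMARYIDs. On the pooled DEMO set — before any drug filtering,
because follow-ups routinely land in later quarters — the FDA rule is
applied per case: keep the most recent FDA_DT, break ties by the largest
PRIMARYID. PRIMARYIDs compare numerically when both sides parse as
integers, else lexicographically on padded strings (FAERS ids are numeric,
but the file stores text). Unparseable FDA_DT values always lose. The
output is sorted by CASEID, so the operation is deterministic, idempotent
and invariant to input order — properties the test suite asserts directly.

## Cohort extraction

The cohort is defined by three filters: a case-insensitive,
whitespace-normalized synonym match on DRUGNAME and PROD_AI (substring or
exact mode); a role-code filter (default: primary suspect only); and an
optional indication filter applied to the INDI rows linked to the matched
drug sequence. Selecting a dose-specific oncology brand by synonym plus
indication, rather than parsing free-text dose fields, is deliberate: dose
fields in spontaneous reports are too dirty to parse reliably, while brand
identity plus indication is exactly how the dose reaches patients.

A large share of real reports carry no INDI rows at all. The default is to
*keep* a matched-drug report with no indication rows when the indication
filter is active (`strict_indication = FALSE`), because silently discarding
that mass would bias the cohort toward well-documented reports; the strict
behavior is available and both are visible in the audit counts. The
shipped synonym and oncology-indication lists are editable defaults, not an
authoritative query.

## The statistics

The counting unit is the (deduplicated report, unique PT) pair — a report
listing a PT twice contributes one unit — and the denominator n is the
total number of units, not reports. This is standard disproportionality
practice and makes the per-PT cells additive: the per-PT `a` values sum to
the cohort's unit total, and a + b + c + d = n for every PT.

ROR = ad/(bc) with the Woolf interval exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)).
Any zero cell makes the estimate or its interval undefined; the row is
flagged rather than corrected, because the positivity criterion's a ≥ 3
floor means a continuity correction could never create a signal anyway. A
Haldane–Anscombe 0.5 correction is available behind a flag for exploratory
use.

The information component is IC = log₂(a·n / ((a+b)(a+c))). The default
implementation is the classic closed-form Bayesian BCPNN with the standard
reference priors (α₁ = β₁ = 1, α = β = 2, γ₁₁ = 1, and γ scaled by the
margins as γ₁₁(n+α)(n+β)/((a+b+α₁)(a+c+β₁))): the reported `ic` is E(IC)
and the bounds are E(IC) ± 2·√V(IC), with IC025 the lower bound. The
variance form matters — the plug-in IC has no finite-sample interval — so a
`raw` mode exists only for the point estimate. The Bayesian estimate
shrinks toward 0 for small counts, which the tests assert on fixed tables,
and both routes are checked against independent brute-force transcriptions
of the closed-form expressions at 1e-9 relative tolerance on randomized
tables.

### Positivity and grading

A PT is a signal only when both methods agree: a ≥ 3 and ROR lower bound
≥ 1 (the bound is read inclusively) and IC025 > 0 (strict). Grades are read
from the lower bounds:

| grade    | ROR lower bound | IC025        |
|----------|-----------------|--------------|
| weak     | [1, 50)         | (0, 1.5]     |
| moderate | [50, 1000)      | (1.5, 3.0]   |
| high     | [1000, ∞)       | (3.0, ∞)     |

The published convention writes the weak ROR band as open at 1; since
positivity already requires the bound to be ≥ 1, the band is closed on the
left here so that the three bands exactly partition the positive range —
every positive bound lands in exactly one grade, including the cutpoints
themselves (50 grades moderate, 3.0 grades moderate on the IC scale). The
"ROR − 1.96SE" notation of the grading convention is interpreted as the
lower 95% CI bound of the ROR, not an additive expression, which is the
only reading consistent with cutpoints at 50 and 1000.

## Descriptives

Sex, age band (<18, 18–64, ≥65, unspecified) and occurrence country each
partition the cohort exactly, with blanks in "Not specified" and countries
beyond the top k collapsed into "Other countries". Seriousness follows the
OUTC table: a report is serious when it has at least one outcome record,
and its primary outcome is the worst under DE > LT > HO > DS > CA > RI >
OT. Because several outcomes can attach to one report, outcome tabulation
offers both a per-report worst-case mode (default) and a per-occurrence
mode; published outcome columns often exceed the report count, so neither
convention can be inferred from totals alone and both are labeled
explicitly.

Time-to-onset is event date minus the *earliest* day-precision start date
among the matched target drug's therapy rows (earliest is the conservative
choice for "time since initiation"); negative gaps and sub-day precision
are missing/invalid. Bins follow the 0–90 / 91–180 / 181–360 / >360 day
cuts, with percentages reported against the whole cohort and, separately,
computable-TTO shares among all and among serious reports.

## The novelty screen

The screen keeps signals that are positive by both methods and graded at
least moderate — keyed on the BCPNN grade, i.e. IC025 > 1.5 under the
default cutpoints, since that is the scale the moderate-plus convention is
stated on; a flag additionally requires the ROR grade — then removes SOCs
that carry no drug-safety meaning (social circumstances, product issues,
surgical and medical procedures) and individual off-label-use style terms,
and splits the remainder by presence on a user-supplied label PT list. An
empty label list is accepted for exploration but warns loudly, since it
flags everything as new.

MedDRA itself is licensed and cannot ship with the package. The bundled
PT→SOC map and label list are small synthetic fixtures covering the
vocabulary used in the examples and tests (filenames and documentation say
so); real analyses must supply a licensed MedDRA export. PTs map to a
single primary SOC — no multi-axiality — so SOC rollups sum exactly to the
number of positive signals.

## The synthetic generator

The generator emulates the structural features of a FAERS extract that the
pipeline must survive: the six-table schema in the exact "$" dialect,
follow-up duplication (a configurable fraction of cases re-emitted with a
later FDA_DT, larger PRIMARYID and identical children), partial and missing
dates, outcome codes, a drug arm selected by brand synonym plus oncology
indication, a 60 mg-brand sibling with a non-oncology indication and a
non-suspect-role slice of the target drug (both of which must be *excluded*
by the cohort filters), and — centrally — injectable disproportionality.

Reports are i.i.d.; each belongs to the target arm with probability
`drug_share` and mentions each vocabulary PT independently with its
baseline probability, multiplied in the target arm by the injected
reporting-rate ratio. Independence per PT makes two things true by
construction: PT draws within a report are automatically unique (matching
the counting unit), and the expected-cell odds ratio of a *single* injected
PT equals its injected ratio exactly, because the injection cancels out of
the b and c margins. With several simultaneous injections each one inflates
the cohort's other-event margin, so expected RORs of other PTs sit slightly
below their injected (or null) values — the familiar masking effect of real
disproportionality analyses. `expected_tables()` returns these closed-form
cells for any configuration and is the oracle the recovery tests compare
against.

Defaults are chosen to look like a serious oncology-support-drug cohort:
2.2 unique PTs per report, 5% target-drug share, 15% follow-up rate, 77%
serious reports with an outcome mix dominated by other-serious and
hospitalization, and a time-to-onset mixture with an early-onset plus
ultra-delayed shape in which about 71% of reports lack computable dates.
Four default injections (ratios 5–60 on osteonecrosis of the jaw,
hypocalcemia, bone pain and giant cell tumor of bone) produce a plausible
signal landscape out of the box.

What the generator does *not* emulate: drug co-prescription structure and
masking by competing drugs, temporal reporting trends across quarters,
correlated event clusters within reports, free-text noise in drug names
beyond simple brand variants, and duplicated cases under *different*
CASEIDs (which the FDA rule cannot catch either). Passing the recovery
tests therefore demonstrates correctness of the counting and statistics on
a clean generative model, not robustness to every pathology of real
spontaneous-report data.

## Numerical choices and degenerate inputs

- Zero cells: ROR flagged undefined, no default correction (see above);
  IC025 from the Bayesian form is finite for a = 0, and raw IC is `NA`
  there.
- An empty contingency table (n = 0) is an error; an empty background
  yields c = d = 0 and undefined RORs rather than a crash.
- Ranking ties (equal case count or ROR) break alphabetically by PT, so
  rankings are reproducible.
- Percentages and report-facing statistics round to 2 decimals; the
  concordance percentage prints at 1 decimal. Internal computation is
  never rounded.
- All text matching (PTs, drug names, indications, label terms) happens on
  lower-cased, whitespace-collapsed strings.
- Every stochastic component flows from a single integer seed; the
  generator restores the caller's RNG state, and equal seeds give
  byte-identical files.

## Problem sizes

The unit tests run on fixtures of a handful of reports and on synthetic
databases of 200–5,000 reports. The parameter-recovery check uses a
200,000-report database with one PT injected at a reporting-rate ratio of
10 over a 0.01 per-report baseline and 119 null PTs, asserting the
estimate within ±20%, interval coverage of the true ratio, dual-method
positivity of the injected PT, and a dual-criteria false-positive rate of
at most 5% over the null PTs. These sizes keep the whole suite in the
low minutes on one CPU while leaving the recovery assertions comfortably
inside sampling tolerance.

## Known limitations

- No stratified or adjusted disproportionality, no PRR/EBGM family, and no
  multiple-testing correction: the dual ROR+BCPNN criterion is the only
  guard against false positives, as is conventional for this design.
- Signal counts and novelty splits are dataset- and dictionary-dependent;
  with the bundled synthetic fixtures they exercise the logic, not any
  real product's label.
- The cohort definition inherits every reporting bias of spontaneous data;
  nothing here estimates incidence or establishes causality.
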