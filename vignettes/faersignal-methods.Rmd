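---
title: "Methods: disproportionality signals and onset profiling for FAERS-style reports"
author: "faersignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signals and onset profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect suspected drug–event reports without
denominators: we see how often a drug is *reported* with an event, never how
often it is *taken*. Disproportionality analysis works around this by asking
whether a drug–event combination is reported more often than the background
of all other reports in the same database. `faersignal` implements that
workflow for a target condition defined by a MedDRA preferred-term (PT)
list — the motivating use case is drug-induced heart failure — from raw
quarterly tables to signal tables, onset profiles and cohort summaries.

## Data model and curation

FAERS quarters arrive as five dollar-delimited ASCII tables keyed by
`primaryid` (a report *version*): DEMO, DRUG, REAC, THER, OUTC. The
`FaersTables` container holds them with an ingest log (rows in = rows kept +
rows dropped, per file). The dialect has no quoting or escaping, so a row
with an embedded delimiter cannot be parsed unambiguously; such rows are
dropped and counted rather than guessed at.

Curation follows the public FDA guidance for the database:

* **Incomplete** reports (missing `primaryid` or `caseid`) are dropped.
* **Incorrect** reports are dropped: unparseable receipt date, or an age of
  150 years and over / weight of 700 kg and over after unit conversion.
  The reporting stream does not define "incorrect" precisely; this
  operationalization is the minimal checkable one and is deliberately
  conservative (junk text in age fields is treated as missing, not as
  grounds for exclusion).
* **Deduplication** keeps one version per `caseid`: the latest `fda_dt`,
  ties broken by the numerically larger `primaryid`. Receipt dates are
  compared as zero-padded digit strings, so a year- or month-precision date
  orders below any full date sharing its prefix — a deterministic total
  order that never imputes days. Detail rows of discarded versions are
  discarded with them, and the operation is idempotent.

## Case finding

A case definition is a set of normalized PTs, optionally with MedDRA codes
(`CaseDefinition`). Matching is exact after trimming, whitespace collapsing
and case folding; when a reaction row carries a code and the definition has
codes, the code decides. There is no substring or fuzzy matching and no
hierarchy traversal: narrow-scope SMQ retrieval is exact-term by
construction, and fuzziness would trade away exactly the specificity the
narrow scope exists to provide. Enlarging a PT list can therefore only grow
the case set (a property the tests exercise).

The package ships the three-PT acute heart failure definition
(`ahfDefinition()`: acute left ventricular failure 10063081, acute right
ventricular failure 10063082, cardiac failure acute 10007556) and an
illustrative heart-failure PT list for testing. The licensed SMQ content is
not redistributable; real analyses supply their own PT export.

## Drug catalog

Drug-level analyses use primary-suspect (PS) records only. Verbatim names
are mapped to ingredients through a plain, user-editable two-column map
(brands, international names, misspellings); unmapped names pass through
normalized, and names explicitly marked ambiguous (`EXCLUDE`) drop the
record, counted. The map loader rejects non-functional or chained entries so
normalization is idempotent. Combination products are their own catalog
entities — a metformin + saxagliptin product is not split into components —
matching how such products are marketed and prescribed. Ranking counts
distinct case reports per ingredient; ties break alphabetically so runs are
reproducible across platforms. ATC level-2 classes come from a second
editable map; one ingredient may map to several classes.

## The signal statistic

For each entity (ingredient or ATC level-2 class) the 2×2 table against the
*entire deduplicated database* is

|          | target event | other events |
|----------|--------------|--------------|
| entity   | a            | b            |
| others   | c            | d            |

with the reporting odds ratio and its Wald interval

$$\mathrm{ROR} = \frac{a\,d}{b\,c}, \qquad
\mathrm{CI}_{95} = \exp\!\Big(\ln \mathrm{ROR} \pm z_{0.975}
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\Big).$$

A signal requires the CI lower bound above 1 **and** a ≥ 3 reports. Three
deliberate choices:

* **No continuity correction.** A zero cell yields an undefined ROR and no
  signal rather than a Haldane-corrected estimate: the a ≥ 3 criterion can
  never act on such tables anyway, and inventing an estimate suggests more
  than the data contain.
* **No multiplicity adjustment.** The output carries raw CIs only, as is
  conventional for hypothesis-generating disproportionality screens; the
  null-calibration simulations below quantify the resulting false-signal
  rate directly.
* **Whole-database background.** Every entity is contrasted against the full
  deduplicated database, not against the other ranked drugs.

Class-level signals pool the distinct reports carrying any PS ingredient of
the class, so a report with two same-class drugs counts once and a
single-drug class reduces exactly to that drug's signal.

## Time to onset and the Weibull shape parameter test

Time to onset (TTO) is the event date minus the earliest therapy start date
among the report's suspect-drug therapy rows, in days. Month-precision dates
impute day 1 on both sides (symmetric, so no directional bias);
year-precision dates are unusable and excluded; non-positive intervals are
excluded (the Weibull log-density is unbounded at 0 for shape < 1). All
exclusions are counted in the `OnsetSample`.

Summaries are the median and quartiles (linear interpolation, reported as
whole days with half-up rounding) and a two-parameter Weibull fit: the
likelihood is maximized over (log α, log β) by BFGS from a moment start —
shape initialized as π/(√6 · sd(log x)), the log-moment estimator, which is
robust for the heavy-tailed β < 1 regime — with convergence tolerance 1e-12
on the relative objective. 95% CIs are Wald intervals on the log scale from
the observed information, transformed back; at the sample sizes involved
(10³–10⁵) these agree with profile-likelihood intervals to well past the
two decimals reported. The shape CI classifies the hazard:

* **early failure** — CI entirely below 1 (risk concentrated after
  initiation, decreasing);
* **random failure** — CI contains 1 (constant hazard);
* **wear-out failure** — CI entirely above 1 (increasing hazard).

The rules partition all valid CIs, with the closed boundaries belonging to
"random failure". The fit refuses samples below a configurable floor
(default 30) rather than returning unstable estimates.

## Demographics

Cohort summaries partition by sex, age (<18, 18–<65, 65–<85, ≥85, unknown;
units DEC/YR/MON/WK/DY/HR converted with 1 DEC = 10 years and calendar-free
divisors 12, 52, 365.25, 8766), weight (<50, 50–<100, ≥100 kg — the
half-open convention resolves the boundary a published table may leave
ambiguous at exactly 100 kg), reporter occupation (physician, pharmacist and
other health professionals vs consumer/lawyer), country (top-k plus Others)
and outcomes (a report may carry several, so that partition alone may exceed
100%). Percentages round half-up — not banker's — to one decimal, which is
what reproduces published table digits; derived ratios (male-to-female
ratio, percent ≥65 among *known-age* reports) round half-up to two decimals.
`characteristicSummary()` rebuilds the summary object from a published count
table so all of this arithmetic can be checked against printed values
without the raw extract.

## The synthetic generator

`generateFaers()` exists so every stage is testable offline, with known
ground truth. Per case it draws one PS drug by marketing share; target-event
status with probability `plantProbability(r, p0)` = r·p0 / (1 − p0 + r·p0),
the probability whose odds are exactly r times the background odds; an onset
interval from the drug's Weibull, with dates derived *backward* from the
event date so every date is parseable by construction; demographics and
outcomes from Table-1-like marginals; and, with the configured probability,
a second, earlier report version differing only in `primaryid`/`fda_dt` —
precisely the fields the deduplication rule keys on. A configurable fraction
of dates is degraded to month precision to exercise the imputation path.

Defaults are the study conditions: background event probability 0.01,
planted multipliers from published drug-level heart-failure signals
(rosiglitazone 44.47, doxorubicin 9.00, metformin 1.14, null for the rest),
pooled onset Weibull(α = 191.02 days, β = 0.49), duplicate rate 0.1. What it
does **not** emulate: free-text misspellings beyond the bundled map,
multi-quarter case evolution, correlated demographics, indication
channeling, or reporting-over-time dynamics. Passing tests therefore
demonstrate correctness of the statistical machinery under the generative
model, not robustness to every pathology of real spontaneous-report data.

## Verification strategy and problem sizes

The test suite pairs every statistic with an independent oracle: the ROR
path against a brute-force scan plus closed-form evaluation on hundreds of
random small databases (agreement to 1e-12 relative); quartiles against the
closed-form Weibull quantile α(−ln(1−p))^{1/β}; the Weibull MLE against an
independent fitter (fitdistrplus) and against the closed-form median
identity α(ln 2)^{1/β}; demographics against a published count table
reproduced digit-for-digit. Recovery experiments use 2×10⁵-case databases
for planted odds multipliers (recovered within a few percent), 100 seeds of
10⁴ cases for null calibration (false-signal rate well under 7.5%, i.e.
1.5× the nominal one-sided 2.5–5%), 62,186 Weibull draws for
shape-parameter recovery (matching the published heart-failure onset sample
size), and 100 repeats at n = 2,000 for CI coverage (≥90% observed for the
nominal 95% Wald interval, the expected finite-n behaviour). These sizes
were chosen as the smallest at which the Monte-Carlo error is comfortably
inside each tolerance.

One caveat worth naming: whole-day reporting makes small quartiles (the
lower quartile of a β ≈ 0.5 onset distribution is ~15 days) discrete in
1-day steps, so quantile checks there allow one day of slack on top of the
5% relative tolerance.

## Limitations

Counts and RORs from the real, full FAERS extract are not reproducible here:
they depend on the licensed SMQ PT list and on tens of millions of reports.
What the package guarantees is the arithmetic: fed the same curated reports
and the same PT list, it computes the same statistics, and every published
number that is a function of published counts is reproduced exactly.
Censoring-aware onset models, fuzzy cross-`caseid` duplicate detection, and
alternative estimators (PRR, BCPNN, EBGM) are out of scope.
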