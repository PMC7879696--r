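---
title: "Disproportionality analysis of spontaneous reports: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersdispro)
```

## The data model and its assumptions

A spontaneous adverse-event report links one case (a patient at a point
in time) to one or more drugs — each with a role: primary suspect,
suspect, concomitant, or interacting — one or more reaction terms,
per-drug indication terms, and coarse demographics (age band, sex,
reporter type). Cases are revised over time; each revision is a separate
record sharing the case identifier. The package models this as a
`report_store`: four flat tables (DEMO, DRUG, REAC, INDI in the public
FAERS ASCII dialect, `$`-delimited with one header line) joined on a
per-revision key, with `dedup_latest()` reducing each case to its
highest version before any analysis. Ties on version fall back to the
later quarter, then to the first record encountered (with a warning):
the revision convention makes "latest version" the canonical view of a
case, but nothing in the file format enforces uniqueness, so the
tie-break must be explicit to keep the pipeline deterministic.

Missing or unrecognized age, sex and reporter values become `"unknown"`
rather than dropping the report: demographic fields are descriptive
here, not eligibility criteria. Country is accepted in DEMO but not
modeled, as no analysis filters on it.

## The statistic

For deduplicated report counts arranged as exposed/comparator ×
event/no-event, the proportional reporting ratio is the ratio of
event-reporting proportions,

$$\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)},$$

with the Wald interval on the log scale,
$\mathrm{SE}(\ln \mathrm{PRR}) = \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}$
and bounds $\exp(\ln \mathrm{PRR} \pm z \cdot \mathrm{SE})$ at
$z = 1.959964$. This is the standard log-Wald construction for the PRR;
applied to the worked-example table (295/62,098 vs 5,565/642,031) it
reproduces the displayed 0.55 (0.49–0.62), which is the consistency
check that pins down the CI formula among its minor variants. Group
comparison uses the Pearson chi-square on the 2×2 without continuity
correction (a `correct` flag enables Yates; at the report counts this
package targets the choice does not move any displayed value).
Significance is the strict inequality `p < alpha` with `alpha = 0.05`.

Numerical choices: statistics are carried at full double precision and
rounded only for display (two decimals for PRR and CI, one for rates per
1000). If either event cell is zero the Haldane–Anscombe correction adds
0.5 to all four cells for the PRR and CI — flagged in the output as
`zero_cell_corrected` — while the chi-square keeps the raw counts; a
group with zero reports is an error (`unanalyzable`), not a value.

## Term sets and matching

Drug, reaction and indication strings are normalized once (lower case,
trademark glyphs stripped, whitespace collapsed) and matched against
named term sets. Drug sets default to substring matching because
verbatim FAERS drug names carry salts, brands and combination-product
strings; reaction and indication preferred terms match exactly. The ten
SGLT2-inhibitor products and the AF pair (atrial fibrillation, atrial
flutter — clinically hard to distinguish, hence pooled) are the study's
verbatim main definitions. The remaining sets — the ATC-A10 comparator
list, anti-arrhythmics, competing-event terms (genitourinary
infections, ketoacidosis, Fournier's gangrene, amputations), indication
sets, and the control events — stand in for an externally curated term
appendix that is not part of the main text: they are **placeholders**,
clearly overridable through the YAML term-set config, and results on
real data depend on completing them. Required disjointness (SGLT2i vs
insulin, AF vs competing events) is asserted when the vocabulary is
built.

One consequence of substring matching is worth noting: combination
products such as "metformin and canagliflozin" legitimately match both
the SGLT2i set and the comparator set (via "metformin"). The default
overlap policy `exclude_from_comparator` — a report listing an SGLT2i is
exposure, never comparator — resolves this the way the active-vs-control
framing implies; `exclude_from_both` and `allow` are selectable because
the grouping rule for dual-listing reports is genuinely underdetermined.

## The filter cascade

Sensitivity analyses are ordered filters over the assigned cohort, each
either excluding reports where a predicate holds or keeping only reports
where it holds (the diabetes-indication restriction). Predicates test
any drug (optionally restricted by role), any indication attached to any
drug of the report, or any reaction. A filter carries a `scope` —
both groups, exposed only, or comparator only — because the insulin
exclusion applies to the comparator group alone, which a scope-less
filter could not express. Every step appends to an attrition table
(reports removed per group per filter), and the battery encodes the
exclusions both as independent analyses and as one fully-combined
analysis, since the study's text treats the final all-filters analysis
as its own result. The primary-suspect sub-analysis restricts the role
in *both* groups, reading the "identified as primary suspect" phrasing
symmetrically. Sex strata drop unknown-sex reports from both strata;
HCP-only keeps physician, other-HCP and pharmacist reporters.

Internal controls close the battery: ibrutinib → AF (expected increase;
its comparator is all other reports, since no natural drug-class
comparator exists for it — an assumption, documented here), and four
SGLT2i controls against the same ATC-A10 comparator: appendicitis and
stroke (expected null), heart failure and chronic kidney disease
(expected decrease). Verdicts are interval-based: increase passes when
the CI lower bound exceeds 1, decrease when the upper bound is below 1,
null when the interval contains 1.

## What the synthetic generator emulates

`generator_config()` defaults encode the study conditions: 62,098
exposed and 642,031 comparator reports, comparator AF rate 8.7/1000,
true reporting-rate ratio 0.55 (the ratio is on *rates*, not odds,
because the PRR is a ratio of proportions), insulin as index drug on 31%
of comparator reports (the share the insulin exclusion removed),
primary-suspect fractions 0.56 and 0.297, a 5,000-report ibrutinib arm
at an AF ratio of 10.6, and 10% duplicate case revisions. Values the
study does not print were fixed once at field-plausible levels:
indication frequencies (diabetes 0.60 — only part of reports specify
it — CVD 0.15, renal 0.05), anti-arrhythmic co-medication 0.03,
demographics matching the described profile (majority ≥ 65, slight male
excess, ~30% consumer reporters), and low competing-event probabilities
(≈2.9% of exposed, ≈0.6% of comparator reports in total).

Masking is mechanistic rather than cosmetic: a report that carries a
competing adverse event suppresses its focal AF reaction with
probability `masking_suppression = 0.8`, so competing-event reports
under-carry AF and inflate the exposed denominator — exactly the
dilution a competing-AE exclusion is meant to repair.
`masking_scenario(config, strength)` scales the exposed arm's competing
probabilities (capped at 1) to study the effect; at the defaults the
residual bias on the main-analysis PRR is ≈0.01, well inside the
recovery tolerance used in the tests.

Negative-control events (appendicitis, stroke) are generated at a true
ratio of 1.0 — the premise of a negative control — rather than at the
noisy observed point estimates, which are measurements consistent with
null at the study's scale; positive-control ratios (heart failure 0.16,
CKD 0.32, ibrutinib 10.6) keep the reported values because their
premise is a real signal. Events are drawn independently of
demographics (the analysis never adjusts for covariates, so correlated
structure would add nothing the tests could detect), reactions outside
the analytic sets come from a filler vocabulary asserted disjoint from
every analytic reaction set, and a fixed seed reproduces the store
byte-for-byte without disturbing the caller's RNG stream.

What the generator does **not** emulate: real FAERS marginal
distributions of drugs and events, temporal reporting trends,
covariate-dependent event rates, free-text noise in drug names beyond
what normalization handles, and reporting-source biases. Passing tests
therefore show the pipeline computes the intended quantities correctly
under the stated stochastic model — not that the placeholders and
assumptions match any particular real FAERS extract.

## Validation design and problem sizes

Every computational stage is checked against an independent oracle:
per-report brute-force enumeration for deduplication, group assignment,
filters and counting; an independent arithmetic route for the PRR and CI
(log-space point estimate, ordered summation for the variance) with
agreement required to at least ten significant digits; an explicit
expected-counts enumeration for the chi-square. Simulation-based checks
use 1,000 binomial tables at the study's arm sizes for CI coverage
(93–97% band), 200 replicate stores of 200,000 reports per arm for
recovery of the true ratio (median within ±0.02 of 0.55), and 100
paired replicates of 20,000 reports per arm under five-fold masking for
the dilution property — 20,000 per arm gives each replicate enough
events (~90 exposed) for the paired comparison to be informative while
keeping the whole suite comfortably fast on one CPU.

## Known limitations

Disproportionality never yields incidence, and a PRR below 1 is not a
protective effect — it is lower *reporting*, which the sensitivity
battery can make more credible but never turns causal. The built-in
non-main-text term sets are placeholders. The CI is the standard
log-Wald form; no Bayesian shrinkage estimators (ROR/IC/EBGM) are
provided, no multiple-testing adjustment is applied across the battery
(mirroring the single-signal study design), and automated
signal-screening thresholds are out of scope.
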