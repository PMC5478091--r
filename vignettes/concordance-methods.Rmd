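---
title: "Evaluating cause-of-death concordance between minimally invasive and complete autopsies"
author: "CoDagree authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating cause-of-death concordance between minimally invasive and complete autopsies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoDagree)
```

## The problem

In settings where most deaths occur without reliable diagnostic work-up,
cause-of-death (CoD) surveillance leans on verbal autopsies and death
certificates of limited specificity. The minimally invasive autopsy (MIA) —
postmortem needle sampling of key organs and fluids, followed by
histopathology and microbiology — has been proposed as a substitute for the
complete diagnostic autopsy (CDA), which is the gold standard but is rarely
acceptable or feasible in such settings. Validating the MIA means asking, for
a series of deaths examined by both methods, how often and how closely the
two verdicts agree.

CoDagree implements that evaluation as a reusable pipeline with four stages:

1. **Evidence grading** — each verdict carries an ordinal pathology level and
   an ordinal microbiology level (both 0–4), combined through a fixed lookup
   matrix into a five-level diagnostic certainty (`no_diagnosis` to
   `very_high`).
2. **Categorization** — each main CoD (an ICD-10 code) is assigned to one of
   five major disease categories: infectious diseases, malignant tumors,
   congenital malformations, other diseases, nonconclusive.
3. **Hierarchical code coincidence** — for category-concordant pairs, how
   deep in the ICD-10 hierarchy (chapter → block → three-character category →
   four-character code) the two codes agree.
4. **Agreement statistics** — Cohen's kappa with two standard errors, overall
   agreement, and per-category sensitivity / specificity / predictive values /
   accuracy with exact binomial intervals.

## Evidence grades and diagnostic certainty

The certainty of a CoD attribution is not modelled; it is specified by a
lookup matrix over the 41 valid combinations of pathology level (0–4),
microbiology level (0–4) and — when both levels are positive — a Y/N flag
stating whether the organisms identified are in concordance with the
histological lesions. The matrix is stored cell-for-cell as data
(`certaintyMatrixTable()`, exported flat in
`inst/extdata/certainty_matrix.tsv`) rather than derived from a rule, because
the table *is* the specification: no formula reproduces, say, the asymmetric
jump from `moderate` to `high` at pathology 2, microbiology 4, flag Y. Two
structural properties hold and are asserted exhaustively in the tests:
certainty is non-decreasing in each evidence level and in the flag, and every
valid cell maps to exactly one level.

One adjustment precedes the lookup: histological identification of a
microorganism associated with inflammatory changes raises the pathology score
by one, capped at 4 (`adjustPathology()`). The flag is cleared on
application, making the operation idempotent; `readCases()` applies it
exactly once per verdict and stores the adjusted levels, so a written and
re-read case file analyses identically.

A verdict is *nonconclusive* exactly when its certainty is `no_diagnosis`;
such verdicts carry a sentinel instead of a code. This iff-invariant is
enforced by the `CaseSet` validity method.

## ICD-10 hierarchy and the coincidence scale

Codes are compared on five tiers: **perfect** (identical full codes —
including the case of two identical three-character codes that have no
fourth-character subdivision, which we read as full-code identity),
**almost perfect** (same three-character category), **moderate** (same
block), **low** (same chapter), **none** (different chapters). The
classification is symmetric, reflexively perfect, and monotone in shared
prefix depth; all three properties are tested over randomly generated codes.

Chapter and block boundaries are shipped as an editable tab-delimited file of
WHO ICD-10 (2016 edition) ranges, because published analyses of this kind
rarely state which edition they used and block boundaries occasionally moved
between editions. Any table can be substituted at run time
(`readBlockTable()`); validity checks reject overlapping blocks and blocks
that escape their chapter. The transport-accident blocks of chapter XX are
collapsed to their section range (V01–V99), a simplification with no effect
on mortality coding of the kind supported here. Chapter XXII (U codes) and
dagger/asterisk suffixes are rejected at parse time.

Category assignment is likewise data, not code: the packaged default map
sends chapter I and the extra-chapter infection blocks (J09–J18, J20–J22,
G00–G09, K65–K67, N10–N16) to infectious diseases, C00–C97 to malignant
tumors, chapter XVII to congenital malformations, R95–R99 to nonconclusive,
and everything else to other diseases. Resolution is most-specific-first
(three-character category > block > chapter > fallback). The map must be
editable because CoD panels categorize by the clinical nature of the
condition — pneumonia (chapter X) and postinfectious peritonitis (chapter XI)
are infectious deaths even though their codes live outside chapter I.

## Agreement statistics

With cell proportions $p_{ij}$ (MIA in rows, CDA in columns), row marginals
$r_i$ and column marginals $c_i$:

$$p_o = \sum_i p_{ii},\qquad p_e = \sum_i r_i c_i,\qquad
\kappa = \frac{p_o - p_e}{1 - p_e}.$$

Two standard errors are computed and both are reported, deliberately. The
*null* SE,

$$SE_0 = \frac{\sqrt{p_e + p_e^2 - \sum_i r_i c_i (r_i + c_i)}}{(1-p_e)\sqrt n},$$

is the one quoted alongside kappa in many reports, but it is only valid for
testing $\kappa = 0$. The confidence interval instead uses the large-sample
variance under the alternative (Fleiss, Cohen and Everitt's formula), which
is what mainstream statistical software computes, and the interval is
truncated to $[-1, 1]$. On the packaged example series the two differ
noticeably (0.0956 vs 0.1102), and quoting the null SE next to an
alternative-based interval is a common source of confusion — hence the
report prints both and labels them. Kappa is interpreted on the Landis–Koch
bands with closed upper bounds (0.61–0.80 substantial, etc.; 0 itself falls
in *slight*).

All proportions — overall agreement and every per-category metric — carry
exact Clopper–Pearson intervals from beta quantiles, with the conventional
one-sided reduction at the boundaries ($k=0$ or $k=n$). Per-category
accuracy is a one-vs-rest collapse: tp is the diagonal cell, fn the rest of
the CDA column, fp the rest of the MIA row, tn the remainder, so the four
cells always sum to $n$. A metric with a zero denominator (the PPV of a
category the MIA never assigned, the sensitivity of a category the CDA never
used) is *not applicable* and is rendered `N/A`, never 0/0.

The coincidence tabulation includes only category-concordant cases, so its
denominator equals the confusion-matrix diagonal sum. A concordant pair of
nonconclusive verdicts would count as perfect (the verdicts are identical);
this degenerate case keeps the denominator invariant exact but does not occur
in the packaged series.

## The packaged example series

The per-case data of the motivating validation study are not publicly
deposited, so the package ships a *synthetic* 54-case series
(`exampleCases()`, file `mia_cda_synthetic_54.csv`) constructed to reproduce
the study's published summary structure exactly: the 5×5 category
cross-tabulation (diagonal 39/7/0/2/0, row totals 42/7/0/3/2, column totals
42/7/2/3/0), the coincidence counts among the 48 concordant cases (32
perfect or almost-perfect, 4 moderate, 3 low, 9 none — the nine `none` pairs
using the study's nine discordant block pairings, e.g. other bacterial
diseases vs influenza and pneumonia), and the per-arm certainty
distributions (CDA 24/20/7/3 very-high/high/moderate/low; MIA 20/17/11/4
plus 2 nonconclusive). Individual codes, ages and sexes are invented;
aggregate behaviour, not case-level truth, is what the fixture fixes. On
this series the pipeline reports $\kappa = 0.70$, null SE 0.0956, 95% CI
0.49–0.92, overall agreement 48/54 (89%), and the full per-category accuracy
table.

```{r example}
report <- evaluateCases(readCases(exampleCasesPath()))
rendered <- renderReport(report)
```

## The synthetic-data generator

`simulateCases()` draws paired verdicts from a `SimDesign`: the CDA (truth)
category from a simplex $\pi$, the MIA category from a row-stochastic
misclassification matrix $M$, codes for concordant pairs constructed to share
exactly a sampled hierarchy depth, and evidence grades drawn to match target
certainty distributions. The implied population kappa is available in closed
form (`analyticKappa()`): $p_o = \sum_i \pi_i M_{ii}$,
$p_e = \sum_j \pi_j (\pi^\top M)_j$.

Design choices worth recording:

* **Defaults are the study conditions.** `simDesign()` defaults encode the
  54-death series: $\pi = (42,7,2,3,0)/54$, $M$ estimated from the observed
  cross-tabulation (with an identity row for the unobserved nonconclusive
  truth category), depth distribution $(24,8,4,3)/48$ with the remaining
  mass on `none`, and the observed certainty distributions. They were fixed
  once, from those conditions, and are not tuning knobs.
* **Codes are synthesized from the block table**, not from a real code
  catalogue: a pair at depth $d$ is built by choosing blocks/categories/
  subcodes that agree exactly to $d$. This avoids shipping the full WHO
  catalogue and makes the depth of agreement exact by construction.
* **Unachievable depths are resampled.** Under the default map the malignant
  category occupies a single chapter, so a cross-chapter `none` pair cannot
  exist within it; the depth is then redrawn from the achievable levels,
  renormalised. Goodness-of-fit tests for the depth distribution therefore
  use an infectious-only design, where all five depths are achievable.
* **Certainty inversion by enumeration.** The 41 valid grade cells are
  grouped by certainty and one cell is drawn uniformly within the sampled
  stratum — the same distribution a rejection sampler would give, at
  deterministic cost.
* Nonconclusive verdicts get the sentinel and a zero grade, preserving the
  code-iff-certainty invariant.

Generation is deterministic given the design seed (the generator saves and
restores the global RNG state).

## What the tests do and do not show

Problem sizes were chosen to make Monte-Carlo conclusions meaningful while
keeping the default suite quick: kappa-oracle equivalence on 1,000 random
matrices; interval coverage on 10,000 binomial draws per scenario; depth
goodness-of-fit at 10,000 cases; large-$n$ kappa convergence at 20,000
cases; parameter recovery as 500 replicates at the study size of 54 (mean
estimated kappa within 3 Monte-Carlo standard errors of the analytic value).

The generator emulates the *structure* the analysis consumes — category
misclassification, code-depth agreement, certainty mix — not the biology
that produces it: no dependence of microbiological recovery on postmortem
interval, no case-mix by age or season, no correlation between certainty and
correctness (in real series, low-certainty verdicts are presumably more
often wrong). Passing parameter-recovery tests therefore shows the pipeline
measures what the generator encodes, not that MIA performs identically in
other populations.

Other known limitations: the category map resolves at block level for
sampling purposes, so explicit three-character overrides are honoured in
classification but not in code pool construction; the kappa interval is a
large-sample approximation, dubious for very small $n$ or near-boundary
kappa even after truncation; and there is no weighted or multi-rater kappa,
and no verbal-autopsy interoperability.
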