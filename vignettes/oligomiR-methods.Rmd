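---
title: "Methods: microRNA qPCR profiling of metastatic progression rate"
author: "oligomiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microRNA qPCR profiling of metastatic progression rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligomiR)
```

## The model and its assumptions

`oligomiR` asks whether microRNA expression in a resected lung metastasis
carries information about how fast a patient's metastatic disease will
progress afterwards. The analysis rests on three modelling commitments:

* **Rate as the phenotype.** Progression is summarized as a rate: the count
  of recurrent metastases divided by the follow-up interval from
  metastasectomy to last follow-up or death (in years). The rate bands —
  LRP below 0.6/yr (patients with no recurrence included), HRP above
  3.6/yr, IRP on the closed interval between — were chosen to spread
  recurrent patients roughly evenly across groups; they are thresholds on a
  continuous quantity, not biological constants, and both are configurable.
  Exact boundary values (0.6, 3.6) classify as IRP because the outer
  classes are defined by strict inequalities. A second, binary phenotype
  (OM/PM) captures the *pattern* of progression: polymetastatic means more
  than 5 new metastases inside any 4-month window, or body-cavity
  progression, within 18 months of first recurrence. When a dated event
  list is available the burst rule is evaluated by a sliding window
  anchored at each event; otherwise a precomputed
  `max_new_mets_in_4_months` field is used. Whether the 18-month window
  includes the first-recurrence lesions themselves is not fixed by the
  definition; we anchor the window at the first recurrence and include it.
* **Ct as log2 expression.** One qPCR cycle is one doubling, so a shift of
  `d` cycles in delta-Ct corresponds to a `2^d`-fold expression change, and
  *higher* Ct means *lower* abundance. Delta-Ct normalization subtracts
  the pooled mean of two endogenous small-RNA controls (RNU-44, RNU-48)
  within each sample, which removes any sample-wide additive offset
  (loading, fixation) exactly — the pipeline's tests assert this shift
  invariance. The signed fold change between groups is
  `+2^(−ddCt)` when that is ≥ 1 and `−2^(+ddCt)` otherwise, with
  `ddCt = mean dCt(HRP) − mean dCt(LRP)`; it is never inside (−1, 1).
* **Unadjusted testing, structure as corroboration.** With 16 vs 32
  samples, per-microRNA t-tests are reported unadjusted (a
  Benjamini–Hochberg column is emitted for information only). The burden
  of evidence is shifted to *structure*: if deregulation is biologically
  real, members of one hairpin family, or the two mature strands of one
  precursor, should move together. That congruence is what the permutation
  statistic quantifies.

## The enrichment statistic

A family (≥ 3 members assayed on the card) is *prioritized* when at least 3
members pass `|fold| ≥ 2` and `p ≤ 0.05` in the same direction (the modal
direction of its significant members; with exactly 3 they must all agree),
and the odds ratio of congruent deregulation — the 2×2 cross-product of
{in family / other assayed} × {prioritized in the modal direction / not},
Haldane–Anscombe 0.5-corrected when a cell is zero — exceeds 3. The
"in-family vs remaining" contrast admits more than one reading; we compare
family members against all other assayed microRNAs because it is the only
variant well defined for every family, and both the contrast and the
correction are configurable. A -3p/-5p pair is prioritized when both
strands pass congruently. The statistic is the total count of prioritized
families plus pairs.

Its null distribution comes from label shuffling: each resampling draws
`n_HRP + n_LRP = 48` samples without replacement from **all 63** (the
intermediate group participates in the shuffles even though it is outside
the observed contrast), assigns 16/32 pseudo-labels, and recomputes the
entire differential table and count. This matches a design in which the
compared groups are a subset of the profiled cohort, and makes the null
account for selection as well as testing. The empirical p-value uses the
add-one convention `(1 + #{null ≥ obs}) / (1 + N)`, so it is bounded below
by `1/(N+1)` and never zero. Tests verify self-consistency (pushing the
true labels through the permutation machinery reproduces the observed
count), invariance to row/column order, and agreement of the Monte-Carlo
null with exhaustive enumeration of label assignments on a 6-sample
instance.

## Clustering and branch enrichment

Samples are clustered with average linkage on `1 − Pearson` correlation
distance, computed across features on pairwise-complete entries with a
minimum overlap of 3 features per sample pair (correlation distance is
scale- and shift-invariant per feature pair, so no feature standardization
is applied; a row-centering option exists for compatibility with classic
expression-clustering software). The partition under the root merge — the
two main dendrogram branches — is cross-tabulated against a binary
phenotype; the odds ratio is the uncorrected cross-product and the p-value
the exact conditional (hypergeometric) two-sided test using the
point-probability rule: sum over all tables with the observed margins whose
point probability does not exceed the observed one. This rule reproduces
published two-tailed Fisher values exactly in our checks (e.g. odds ratio
7.2 with p = 0.047 for an 8/5 vs 2/9 table) and is verified against a full
`choose()`-based enumeration for every 2×2 table of total ≤ 20. A mid-p
variant exists but is off by default.

Branch recall gets a central 90% (5%–95%) binomial interval from the
F-distribution form of the Clopper–Pearson bounds; a Jeffreys-prior
Bayesian variant is available (`method = "jeffreys"`). For 13/16 the
Clopper–Pearson bounds are 58.3%–94.7% and Jeffreys gives 61.9%–92.9%;
neither matches a published 56%–93% interval exactly, so the precise
published variant is under-determined and we document rather than assert
it.

## Survival

Kaplan–Meier estimation and the Mantel–Cox log-rank test are delegated to
the `survival` package; the group median is defined as the first time the
survival function reaches 0.5 or below (reported as missing when the curve
never does — not as infinity). Deaths are processed before censorings at
tied times, the standard convention. Mann–Whitney tests use the exact
distribution for ≤ 12 observations per group without ties and the
tie-corrected normal approximation otherwise (no continuity correction, so
identical samples give p = 1); Spearman correlations use exact enumeration
for n ≤ 9 without ties and the t-approximation otherwise.

## What the synthetic cohort emulates — and what it does not

`generateCohort()` simulates the study conditions: 63 patients (32 LRP, 16
HRP, 15 IRP), a 376-microRNA card plus two controls, and survival medians
of 63.5 (LRP), 18 (HRP) and 30 (IRP) months.

* **Recurrence.** Each patient's recurrent-metastasis count is a Poisson
  draw over their follow-up with a group-specific yearly intensity (LRP:
  zero-inflated 0.05–0.5; IRP: 0.9–3.2; HRP: 4.5–9), re-drawn until the
  recomputed rate lands in the planted band so that re-running the
  stratification rule recovers the planted label exactly. An
  intermediate-rate label is only attainable when follow-up is long enough
  for an integer count to land in the band, so IRP survival is
  left-truncated at 6 months. The time to first recurrence is pinned near
  the expected first order statistic of the event process,
  `followup/(n+1)`, with lognormal jitter scaled by
  `1 − rate_time_coupling` (default coupling 0.8). This yields Spearman
  correlations between rate and time-to-first-recurrence of about −0.95
  across seeds, comfortably beyond the −0.8 the analysis assumes.
* **Phenotype nesting.** Every HRP patient meets a PM criterion (a
  cavity-progression flag is planted whenever the event process itself
  shows no >5-in-4-months burst) and LRP counts are capped at 4 recurrent
  metastases, so no LRP patient can be PM. The HRP⊂PM / LRP⊂OM nesting is
  therefore a property of the generator, asserted on its output — not a
  logical consequence of the classification rules.
* **Survival.** Exponential per group with uniform administrative
  censoring on 16–120 months; a 200-per-group cohort recovers the planted
  63.5/18-month medians within 20%.
* **Expression.** Per-microRNA baselines are uniform on 22–33 Ct (10% of
  assays sit at 34.5–37.5 to exercise dropout), each sample has a global
  offset (removed exactly by delta-Ct), controls are generated at CV below
  2%, and wells whose latent Ct exceeds the dropout threshold (default 38)
  become missing — dropout removes entries but never alters retained
  values. The default planted signal mirrors the discovery comparison's
  shape: 40 shifted microRNAs (37 down in HRP at 1.5–3.011 cycles, 3 up),
  covering one complete 4-member family and two complete -3p/-5p pairs;
  the card layout provides exactly 15 evaluable families and 50 complete
  pairs. The per-well noise default of 1.65 cycles (≈ 3-fold
  between-patient variability, typical of archival tumor qPCR) was
  calibrated once against the structural targets above: it places the
  permutation test's rejection rate on pure-noise cohorts near its nominal
  5% level while keeping a single planted 3-cycle family detectable at
  median empirical p < 0.05.
* **Not emulated.** Real arrays have correlated microRNAs (co-regulation,
  shared processing), batch structure, and heavier-tailed noise. The
  independent-noise generator therefore has a *thinner* permutation null
  than real data: a planted-enrichment empirical p on synthetic data is
  smaller than what the same observed count would earn on a real cohort.
  Passing tests demonstrate correctness of the machinery and calibration
  under the generator's assumptions, not performance on real tissue.

## Numerical choices and degenerate inputs

* Row-wise t-statistics are computed by vectorized matrix arithmetic
  (pooled-variance Student by default, Welch by option) because the
  permutation loop recomputes ~376 tests × 10,000 resamplings; unit tests
  pin them to `stats::t.test` to 1e-12. Rows whose pooled spread is zero up
  to floating-point rounding (tolerance `1e-9` relative to the means) are
  treated as exactly degenerate: p = 1 when the means agree, p = 0
  otherwise. MicroRNAs with fewer than `minN = 3` observations per group
  (after missingness) are skipped and logged, not fatal.
* Quantile normalization operates on OK-flagged entries only and leaves
  missing entries missing; unequal per-sample counts of available values
  are handled by interpolating the mean quantile function
  (`limma::normalizeQuantiles`), which preserves the observed marginal
  distributions.
* Sorting of prioritized tables breaks fold-change ties lexicographically
  by microRNA id, for deterministic output.
* Detectability thresholds differ across QC dialects on real cards (230
  and 190 appear in different stages of array QC); both the threshold and
  the dialect are configuration, with 230/Ct<38 the discovery default and
  the 10/37 flag rules the validation default.
* Every stochastic step (generation, permutation) takes an explicit
  integer seed and is bit-reproducible; the pipeline manifest records
  seeds, thresholds and input checksums.

## Problem sizes used in validation

The shipped test suite exercises: the full 63-patient default cohort (and
a 200+200 survival cohort); permutation calibration at 1,000 resamplings
over 100 pure-noise cohorts plus 21 planted cohorts; exhaustive Fisher
verification over all ~8,800 2×2 tables of total ≤ 20; and the acceptance
script runs the enrichment test at the full 10,000 resamplings. These sizes
were chosen to estimate each quantity to well inside its acceptance band.

## Known limitations

* The rate denominator runs from surgery to last follow-up or death; ties
  between death date and a same-day follow-up are resolved in favor of
  death.
* The enrichment odds-ratio contrast and the two-branch dendrogram cut are
  each one of several defensible readings; both are exposed as options
  rather than hard-coded alternatives.
* Published proportion intervals of the "Bayesian F-distribution" type are
  under-determined (see above); we provide the two standard variants.
* No amplification-efficiency modelling, no batch correction, and no
  platform binary parsing: inputs are plain Ct tables.
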