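---
title: "Evidence-integrated miRNA target scoring: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-integrated miRNA target scoring: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtev)
library(dplyr)
```

## The scoring model

A microRNA represses its target mRNAs, so four independent kinds of data
each leave a footprint when a pair (miRNA *m*, gene *g*) is a genuine
regulatory relationship: *g* goes down when *m* is ectopically expressed,
up when *m* is knocked out or knocked down, the two are anti-correlated
across tumors, and sequence-based algorithms call *g* a target of *m*.
mirtev condenses each category into a **partial score**: 100 times the
fraction of that category's datasets supporting the pair,

* ectopic: fraction of datasets with linear fold change (treated/control)
  strictly below `fc_down` = 0.8 (i.e. repression by more than 1.25-fold);
* knockout/knockdown: fold change strictly above `fc_up` = 1.25;
* correlation: Pearson coefficient strictly below `r_cut` = -0.1, one
  datapoint per cancer entity;
* prediction: positive calls divided by the *configured* algorithm
  complement (ten tools by default), not by the number of tools that
  happened to report the pair.

Threshold counting rather than per-dataset significance is deliberate:
many of the expression datasets such compendia are built from are
unreplicated, so no per-dataset p-value exists; a >25 % change is treated
as the biologically relevant effect size. Each partial therefore lies in
[0, 100] with ceiling 100.

The **composite score** is the equally weighted mean of the partial scores
of the categories that have data for the pair: the sum of present partials
divided by the count of present categories. With all four categories this
is the divide-by-4 rule that puts the maximum at 100; for miRNAs with no
perturbation data at all it reduces to (correlation + prediction) / 2.
When exactly one experimental category is missing we divide by 3 —
"weigh equally" applied to whatever is present. This generalization is a
design choice of this package (the two printed cases do not pin it down);
the `availability` mask (`"EKCP"` subsets) records which categories
entered every composite so downstream consumers can filter on it.

Two asymmetric conventions matter:

* **No data is not contradicting data.** A dataset that did not measure a
  gene is excluded from both numerator and denominator, and a pair with no
  evidence in any category is omitted from the table rather than scored 0.
  Only the prediction partial is always defined (0 calls / complement).
* **Ranks are bijections.** Within a miRNA, genes are ranked 1..N by
  descending composite (`mirna_rank`); within a gene, miRNAs likewise
  (`mrna_rank`). Ties break on the lexicographically smaller identifier,
  so ranks are deterministic and invariant to row order.

```{r toy}
partial_ectopic(c(0.5, 0.7, 0.9))          # 2 of 3 datasets repressed
composite_score(100, 60, 90.625, 80)       # all four categories present
composite_score(NA, NA, 90, 70)            # correlation + prediction only
```

## Clinical annotations

Cancer relevance is attached per feature (gene or miRNA) and entity:

* **Differential expression** between tumor and normal samples uses the
  moderated t-statistic (empirical-Bayes shrinkage of gene-wise variances
  via limma), BH-adjusted within entity; direction labels
  (`up_in_tumor` / `down_in_tumor`) require adjusted p < `alpha` (0.05),
  configurable to raw p. Features with constant expression or median zero
  are `undetermined` — the operationalization chosen here for "could not
  be determined due to low expression"; the exact floor is a free choice
  and is exposed in one place.
* **Survival association** dichotomizes expression at the cutoff
  maximizing the log-rank statistic over the unique expression values
  between the 10th and 90th percentile that leave at least 10 % of the
  cohort in each group (maximally selected rank statistic). The reported
  p-value is the naive log-rank p at the chosen cutoff — faithful to the
  widely used cutoff-finding tooling, and therefore **anti-conservative
  under the null**: selecting the best of ~n candidate splits inflates the
  type-I rate several-fold. The test suite asserts this inflation as a
  property rather than hiding it; treat these p-values as a screening
  ranking, not calibrated inference. The hazard ratio comes from a
  univariate Cox fit on the binary indicator.
* **Dependency**: a gene is flagged in an entity when at least 10 %
  (inclusive) of its cell lines have a gene-effect score strictly below
  -0.5; the fraction below -1 is reported as essentiality. CRISPR and
  RNAi screens are kept as separate calls.
* **Druggability** is case-insensitive membership in a user-supplied list.

One symmetry worth knowing: negating the expression vector mirrors the
high/low split exactly (identical log-rank p, reciprocal hazard ratio,
opposite direction label). The superficially similar operation of swapping
the event indicator does *not* invert the direction — with independent
censoring the swapped "events" are censoring times whose hazard carries no
group signal — so no such behavior is promised or tested.

## Summary scores, benchmarking, enrichment

The per-miRNA **clinical summary scores** take the miRNA's top-`k`
(default 1000) targets by `mirna_rank` and sum +1/-1/0 contributions:
+1 for a target significantly up in tumors (or associated with poor
survival), -1 for down (good survival), 0 otherwise. Genes missing an
annotation contribute 0 rather than being dropped, keeping the sum over a
fixed-size set comparable across miRNAs. A strongly positive tumor/normal
score therefore reads "this miRNA's targets are predominantly
overexpressed in tumors" — the signature expected of a tumor-suppressive
miRNA's target set.

**Benchmarking** asks whether externally validated targets concentrate at
the top of each miRNA's ranking: for every miRNA with at least 10
validated targets (luciferase-reporter records by default), a preranked
GSEA of the validated set against the full ranked gene list. The
enrichment score is the weighted Kolmogorov–Smirnov running sum (weight
exponent 1); the null permutes set membership over gene labels;
p-values are the sign-matched tail with +1 smoothing (so p is never below
1/(n_perm+1)); NES divides the observed ES by the mean |permuted ES| of
matching sign. Ties in the ranking break by gene identifier so the ES is
deterministic. Degenerate sets are handled explicitly: empty overlap gives
p = 1 with a warning, a set covering the whole ranking has no defined
deviation and reports ES = 0.

**Over-representation** of a query list in gene sets (GMT collections, or
the top-`k` target set of every miRNA for the "which miRNA drives my
signature" question) is the one-sided hypergeometric tail with BH
adjustment across sets. The universe defaults to all genes in the score
table; this is a documented choice, not an inference — published analyses
of this kind rarely state their universe, and the universe changes p-values
materially.

## The synthetic-fixture generator

`generate_evidence()` and `generate_clinical()` produce complete inputs
with planted ground truth so every pipeline stage is testable offline.
The defaults emulate the real compendia's proportions at small scale:
about four ectopic and three knockout studies per miRNA, a two-digit
number of correlation entities, a 10-tool prediction complement, and 5 %
of genes planted as true targets per miRNA.

Noise models were chosen for closed-form expectations, not realism:
log-normal fold-change noise (planted ectopic fold 0.5, knockout 2.0,
sdlog 0.15; decoys centred on 1 with sdlog 0.25), Fisher-z jitter around
a planted correlation of -0.4 (sd 0.15), binomial prediction support
(mean 8/10 planted, per-tool rate 0.05 for decoys), 90 % measured cells
per dataset. Each miRNA carries a clinical class — `suppressor` (down in
tumors, good survival, targets up/poor and partly dependent/druggable) or
`oncomir` (mirror) — and `generate_clinical()` realizes it: tumor/normal
log2 shifts of ±1.5, survival via a latent per-patient risk that planted
poor-survival features load on (loading 0.8, log-hazard slope log 2.5,
exponential times with uniform censoring), dependency effects at a planted
30 % dependent-line fraction.

What passing tests on these fixtures do **not** show: behavior under
transcriptome-wide correlation structure, batch effects, platform-specific
missingness, or miRNA-family cross-targeting beyond the constructed cases.
They establish that the arithmetic is right and that planted signal of
realistic size is recovered; external validity rests on the upstream data,
not on this package.

## Numerical choices and problem sizes

* All category thresholds are strict inequalities, read literally from the
  scoring formula; boundary cases (fold change exactly 0.8 or 1.25,
  r exactly -0.1, effect exactly -0.5) do not count as support.
* The dependency fraction threshold is inclusive (>= 10 %), exhaustively
  verified for every k/n with n <= 50.
* Score tables serialize doubles at 17 significant digits so write/read
  round-trips are bit-exact.
* Permutation seeds are explicit arguments everywhere; the generator's
  outputs are byte-identical across runs for a fixed seed, and the
  preranked GSEA restores the caller's RNG state.
* Test and benchmark problem sizes are deliberately small — bundles of
  6–20 miRNAs over 150–2000 genes, cohorts of 40–200 patients, 100–500
  permutations or seeds — the scale at which the suite's Monte-Carlo
  checks (planted-vs-decoy AUC, survival direction recovery, null
  calibration) are already stable.

## Known limitations

* The selected-cutoff survival p-value is uncorrected by design (see
  above); the candidate-filter queries built on it inherit the optimism.
* Identifiers are opaque case-insensitive strings; no alias or ortholog
  resolution is attempted, so inputs must share a naming convention.
* The composite weighs a category with one dataset as heavily as one with
  fifty; the per-category `(support, total)` counts are exposed so users
  can apply their own evidence-volume filters.
* Whether a prediction tool that lacks a miRNA entirely should count as
  0/complement (the behavior here) or be dropped from the denominator is
  unresolvable from first principles; the complement is configurable.
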