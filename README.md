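# mirtev

Evidence-integration scoring of microRNA targets, with cancer-relevance
annotations, for computational biologists who want a reproducible,
scriptable version of the integrative target-ranking workflow: given
perturbation compendia, tumor expression correlations and prediction-tool
calls, rank candidate targets of a miRNA (or candidate miRNA regulators of
a gene), attach per-cancer clinical annotations, and ask enrichment
questions about the resulting target sets.

## The score

For a pair (miRNA *m*, gene *g*), each of four evidence categories yields a
partial score = 100 × (supporting datasets / total datasets):

| category | support criterion (strict) | default cutoff |
|---|---|---|
| ectopic miRNA expression | fold change FC < `fc_down` | 0.8 |
| miRNA knockout/knockdown | FC > `fc_up` | 1.25 |
| tumor miRNA–mRNA correlation | Pearson r < `r_cut` | −0.1 |
| prediction algorithms | positive calls / complement | 10 tools |

The composite score is the mean of the partial scores of the categories
with data,

    S(m, g) = ( Σ_c present  P_c(m, g) ) / #present ∈ [0, 100],

which is Σ P_c / 4 when all four categories are present and the printed
(correlation + prediction) / 2 fallback when a miRNA has no perturbation
data. Pairs with no evidence anywhere are omitted, not scored 0. Genes are
ranked per miRNA and miRNAs per gene by descending composite with
deterministic tie-breaking.

On top of the score table the package provides: limma-moderated
tumor/normal differential expression; optimal-cutoff (maximally selected)
log-rank survival association with Cox hazard ratios; DepMap-style
dependency flags (≥ 10 % of cell lines with gene effect < −0.5);
druggability flags; per-miRNA ±1 clinical summary scores over the top-1000
targets; preranked-GSEA benchmarking against validated-target catalogs;
hypergeometric over-representation of gene lists against per-miRNA target
sets; criteria-based candidate filtering; and per-pair JSON detail
reports. A seeded synthetic-fixture generator with planted ground truth
makes the whole pipeline runnable and testable without any download.

## Worked example

```r
library(mirtev)

sim    <- generate_evidence(n_mirnas = 6, n_genes = 300, n_entities = 6, seed = 42)
scores <- score_targets(sim$bundle)
glance(scores)
#> # A tibble: 1 × 6
#>   n_pairs n_mirnas n_genes mean_composite median_composite max_composite
#>     <int>    <int>   <int>          <dbl>            <dbl>         <dbl>
#> 1    1800        6     300           21.0             16.7           100

head(scores[c("mirna", "gene", "ectopic", "knockout", "correlation",
              "prediction", "composite", "mirna_rank")], 3)
#>     mirna     gene ectopic knockout correlation prediction composite mirna_rank
#> 1 miR-001 GENE0024     100      100         100         90      97.5          1
#> 2 miR-001 GENE0146     100      100         100         90      97.5          2
#> 3 miR-001 GENE0153     100      100         100         90      97.5          3
```

Every row is one scored pair: the four partials (100 = every dataset in
the category supports the pair; the prediction partial of 90 means 9 of
the 10 configured tools call it), their mean as the composite, and the
gene's rank among that miRNA's targets. The generator planted these pairs
as true targets, so they top the ranking.

Benchmarking the table against the generator's validated-target catalog —
a preranked GSEA of each miRNA's validated set against its ranked gene
list — finds all six miRNAs significantly enriched:

```r
bm <- benchmark_validated(scores, sim$ledger$catalog, min_targets = 5,
                          n_perm = 500, seed = 7)
glance(bm)
#> # A tibble: 1 × 3
#>   n_tested n_significant alpha
#>      <int>         <int> <dbl>
#> 1        6             6  0.05
head(bm[c("mirna", "size", "es", "nes", "p", "fdr")], 3)
#>     mirna size    es  nes       p     fdr
#> 1 miR-001    7 0.973 2.16 0.00228 0.00239
#> 2 miR-002    7 0.973 2.15 0.00227 0.00239
#> 3 miR-003    7 0.973 2.17 0.00235 0.00239
```

An enrichment score of 0.97 with NES ≈ 2.2 and FDR < 0.003 says the seven
validated targets sit essentially at the top of the 300-gene ranking.
From here, `annotate_clinical()` + `filter_candidates()` answer queries
like "druggable targets of this miRNA that are up in tumors and associated
with poor survival in at least half the cancer types", and
`detail_report()` emits the full per-pair evidence dossier as JSON.

A command-line front end wraps the same functions
(`inst/cli/mirtev.R`; subcommands `simulate`, `score`, `annotate`,
`target-scores`, `benchmark`, `enrich-list`, `query`, `detail`), and the
methods vignette (`vignettes/evidence-scoring.Rmd`) documents the model,
its assumptions and the generator's design.

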