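Package: mirtev
Title: Evidence-Integration Scoring of microRNA Targets with Cancer Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates four categories of microRNA target evidence --
    transcriptome fold changes after ectopic miRNA expression, fold changes
    after miRNA knockout or knockdown, pan-cancer miRNA/mRNA expression
    correlations, and binary calls from sequence-based prediction algorithms --
    into a composite per-pair target prediction score with bidirectional
    ranks. Attaches cancer-relevance annotations (moderated tumor-vs-normal
    differential expression, optimal-cutoff log-rank survival association,
    cell-line dependency flags, druggability), aggregates them into per-miRNA
    clinical summary scores over top-ranked targets, benchmarks score quality
    by preranked gene-set enrichment against validated-target catalogs,
    supports over-representation analysis of target sets and user gene lists,
    and answers filtered candidate queries with per-pair detail reports.
    Ships a seeded synthetic-fixture generator with planted ground truth so
    the full pipeline is testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    limma,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    withr
Config/testthat/edition: 3
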