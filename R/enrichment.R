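#' Build a ranked gene list from a score table
#'
#' Extracts one miRNA's genes ordered by descending composite score with
#' deterministic tie-breaking by gene symbol, as a named numeric vector
#' suitable for [preranked_gsea()].
#'
#' @param scores An `mt_scores` table.
#' @param mirna One miRNA identifier.
#' @return Named numeric vector, names = genes, strictly rank-ordered.
#' @export
ranked_list <- function(scores, mirna) {
  rows <- scores |>
    filter(tolower(.data$mirna) == tolower(.env$mirna)) |>
    arrange(desc(.data$composite), .data$gene)
  if (nrow(rows) == 0) {
    abort(sprintf("miRNA '%s' is not in the score table", mirna), class = "mt_lookup_error")
  }
  setNames(rows$composite, rows$gene)
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score (weight exponent 1).
# `hits` is a logical vector along the ranking. The extremum of larger
# magnitude is the ES; with a zero-weight hit set the hit increments fall
# back to equal steps.
gsea_es <- function(stats, hits) {
  n <- length(stats)
  n_hit <- sum(hits)
  if (n_hit == 0 || n_hit == n) return(NA_real_)
  w <- abs(stats)
  wsum <- sum(w[hits])
  inc <- numeric(n)
  if (wsum > 0) inc[hits] <- w[hits] / wsum else inc[hits] <- 1 / n_hit
  inc[!hits] <- -1 / (n - n_hit)
  running <- cumsum(inc)
  i <- which.max(abs(running))
  running[i]
}

#' Preranked gene-set enrichment
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment (weight exponent 1)
#' of a gene set in a ranked list, with gene-label permutations: the null
#' re-draws the hit positions uniformly, NES is the observed ES divided by
#' the mean |permuted ES| of matching sign, and the permutation p-value is
#' the sign-matched tail with +1 smoothing (so `p >= 1/(n_perm + 1)`).
#' Fully reproducible under `seed`.
#'
#' A set with no overlap returns `p = 1` with a warning; a set covering the
#' entire ranking has no defined deviation and returns `es = 0` with a
#' warning.
#'
#' @param ranked Named numeric vector (see [ranked_list()]) or a two-column
#'   data frame `(gene, score)`; sorted internally by descending score with
#'   ties broken by gene symbol.
#' @param gene_set Character vector of gene symbols.
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param seed Integer seed.
#' @param set_name Label recorded in the result.
#' @return One-row tibble `(set_name, size, es, nes, p, fdr)` with class
#'   `mt_enrichment` (`fdr` is `NA` here; it is filled when several results
#'   are collected, e.g. by [benchmark_validated()]).
#' @export
preranked_gsea <- function(ranked, gene_set, n_perm = 1000, seed = 1L,
                           set_name = "set") {
  ranked <- as_ranked(ranked)
  stats <- ranked$score
  genes <- ranked$gene
  hits <- tolower(genes) %in% tolower(unique(gene_set))
  n_hit <- sum(hits)
  res <- tibble(set_name = set_name, size = n_hit,
                es = NA_real_, nes = NA_real_, p = 1, fdr = NA_real_)
  if (n_hit == 0) {
    warn(sprintf("gene set '%s' has no overlap with the ranking", set_name))
    return(new_enrichment(res))
  }
  if (n_hit == length(genes)) {
    warn(sprintf("gene set '%s' covers the entire ranking; ES undefined, reported 0", set_name))
    res$es <- 0
    return(new_enrichment(res))
  }

  es <- gsea_es(stats, hits)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  n <- length(stats)
  perm_es <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, n_hit)
    h <- logical(n); h[idx] <- TRUE
    gsea_es(stats, h)
  }, double(1))

  same_sign <- if (es >= 0) perm_es >= 0 else perm_es < 0
  n_same <- sum(same_sign)
  p <- (sum(same_sign & abs(perm_es) >= abs(es)) + 1) / (n_same + 1)
  denom <- if (n_same > 0) mean(abs(perm_es[same_sign])) else NA_real_
  nes <- if (!is.na(denom) && denom > 0) es / denom else NA_real_

  res$es <- es; res$nes <- nes; res$p <- p
  new_enrichment(res)
}

as_ranked <- function(ranked) {
  if (is.numeric(ranked) && !is.null(names(ranked))) {
    ranked <- tibble(gene = names(ranked), score = unname(ranked))
  } else {
    ranked <- as_tibble(ranked)
    need_columns(ranked, c("gene", "score"), "ranked list")
  }
  if (anyDuplicated(tolower(ranked$gene))) {
    abort("ranked list contains duplicate genes", class = "mt_validation_error")
  }
  arrange(ranked, desc(.data$score), .data$gene)
}

new_enrichment <- function(x) {
  class(x) <- unique(c("mt_enrichment", class(as_tibble(x))))
  x
}

#' Benchmark a score table against a validated-target catalog
#'
#' For every miRNA with at least `min_targets` validated targets of the
#' required assay class present in the catalog, runs [preranked_gsea()] of
#' its validated set against its full ranked score list, then BH-adjusts
#' the permutation p-values across miRNAs. A positive enrichment score
#' means validated targets concentrate among the top-scored genes.
#'
#' @param scores An `mt_scores` table.
#' @param catalog Validated-target catalog tibble
#'   (see [read_target_catalog()]).
#' @param min_targets Minimum validated targets for a miRNA to qualify.
#' @param assay Required assay class (`"luciferase_reporter"` gold
#'   standard); use `NULL` to accept all records.
#' @param n_perm,seed Permutation settings, see [preranked_gsea()].
#' @param alpha Significance level for the summary count.
#' @return `mt_enrichment` tibble, one row per qualifying miRNA
#'   `(mirna, set_name, size, es, nes, p, fdr, significant)`, with
#'   attribute `summary` = list(n_tested, n_significant, alpha).
#' @export
benchmark_validated <- function(scores, catalog, min_targets = 10,
                                assay = "luciferase_reporter",
                                n_perm = 1000, seed = 1L, alpha = 0.05) {
  need_columns(catalog, c("mirna", "gene"), "validated-target catalog")
  if (!is.null(assay) && "assay" %in% names(catalog)) {
    catalog <- catalog |> filter(.data$assay %in% .env$assay)
  }
  sets <- catalog |>
    distinct(.data$mirna, .data$gene) |>
    group_by(.data$mirna) |>
    summarise(genes = list(.data$gene), n = n(), .groups = "drop") |>
    filter(.data$n >= min_targets, tolower(.data$mirna) %in% tolower(unique(scores$mirna)))

  if (nrow(sets) == 0) {
    warn("no miRNA meets the validated-target minimum; empty benchmark")
    out <- tibble(mirna = character(), set_name = character(), size = integer(),
                  es = double(), nes = double(), p = double(), fdr = double(),
                  significant = logical())
    return(new_enrichment(out))
  }

  out <- purrr::map_dfr(seq_len(nrow(sets)), function(i) {
    m <- sets$mirna[i]
    r <- preranked_gsea(ranked_list(scores, m), sets$genes[[i]],
                        n_perm = n_perm, seed = seed + i, set_name = "validated_targets")
    mutate(r, mirna = m, .before = 1)
  })
  out$fdr <- p.adjust(out$p, "BH")
  out$significant <- out$fdr < alpha & !is.na(out$es) & out$es > 0
  attr(out, "summary") <- list(n_tested = nrow(out),
                               n_significant = sum(out$significant),
                               alpha = alpha)
  new_enrichment(out)
}

#' Over-representation analysis (one-sided hypergeometric)
#'
#' For each gene set, tests whether the query list overlaps it more than
#' expected when drawing `n = |query \strong{within} universe|` genes from the
#' universe: `p = P[X >= k]` with
#' `X ~ Hypergeometric(N = |universe|, K = |set in universe|, n)`.
#' BH-adjusted across sets.
#'
#' @param query Character vector of gene symbols.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of background genes.
#' @return `mt_enrichment` tibble, one row per set:
#'   `(set_name, k, n, K, N, odds_ratio, p, fdr, overlap_genes)`
#'   ordered by p.
#' @export
ora_enrich <- function(query, sets, universe) {
  query <- unique(tolower(query))
  universe_canon <- normalize_ids(universe, axis = "gene")
  uni <- tolower(universe_canon)
  query <- intersect(query, uni)
  if (length(query) == 0) {
    abort("query has no overlap with the universe", class = "mt_input_error")
  }
  N <- length(uni); n <- length(query)
  out <- purrr::map_dfr(seq_along(sets), function(i) {
    set <- intersect(unique(tolower(sets[[i]])), uni)
    K <- length(set)
    overlap <- intersect(query, set)
    k <- length(overlap)
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- if (k == 0 || K == 0) 0 else (k / (n - k + 0.5)) / ((K - k + 0.5) / (N - K - n + k + 0.5))
    tibble(set_name = names(sets)[i] %||% as.character(i),
           k = k, n = n, K = K, N = N, odds_ratio = or, p = p,
           overlap_genes = paste(universe_canon[match(overlap, uni)], collapse = ","))
  })
  out$fdr <- p.adjust(out$p, "BH")
  out <- arrange(out, .data$p, .data$set_name)
  new_enrichment(out[c("set_name", "k", "n", "K", "N", "odds_ratio", "p", "fdr", "overlap_genes")])
}

#' Which miRNAs' targets are enriched in a user gene list?
#'
#' Builds the top-`k` predicted target set of every miRNA in the score
#' table and runs [ora_enrich()] of the user's list against those sets —
#' answering "which miRNAs are likely behind this expression signature".
#'
#' @param user_genes Character vector of gene symbols (e.g. the most
#'   downregulated mRNAs after a miRNA mimic transfection).
#' @param scores An `mt_scores` table.
#' @param k Top-set size per miRNA.
#' @param universe Background genes; defaults to every gene in the score
#'   table.
#' @return `mt_enrichment` tibble as in [ora_enrich()], one row per miRNA
#'   (set names are miRNA identifiers), ordered by FDR.
#' @export
user_list_mirna_enrichment <- function(user_genes, scores, k = 1000, universe = NULL) {
  universe <- universe %||% unique(scores$gene)
  mirnas <- unique(scores$mirna)
  sets <- lapply(setNames(mirnas, mirnas), function(m) {
    suppressWarnings(extract_top_targets(scores, m, k))
  })
  out <- ora_enrich(user_genes, sets, universe)
  arrange(out, .data$fdr, .data$p, .data$set_name)
}
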