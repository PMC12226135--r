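test_that("enrichment score matches the brute-force running-sum oracle", {
  stats <- setNames(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1), paste0("g", 1:10))
  cases <- list(
    paste0("g", 1:3),                # block at the top
    paste0("g", c(2, 5, 9)),         # scattered
    paste0("g", 8:10),               # block at the bottom
    paste0("g", c(1, 10)),
    "g5"
  )
  for (set in cases) {
    res <- preranked_gsea(stats, set, n_perm = 100, seed = 1)
    hits <- names(stats) %in% set
    expect_equal(res$es, brute_es(unname(stats), hits), tolerance = 1e-12)
  }
  # frozen oracle values
  expect_equal(preranked_gsea(stats, paste0("g", 1:3), n_perm = 100, seed = 1)$es,
               1, tolerance = 1e-12)
  expect_equal(preranked_gsea(stats, paste0("g", c(2, 5, 9)), n_perm = 100, seed = 1)$es,
               0.453781512605042, tolerance = 1e-12)
})

test_that("enrichment score agrees with the independent fgsea implementation", {
  skip_if_not_installed("fgsea")
  set.seed(21)
  stats <- setNames(sort(rnorm(60), decreasing = TRUE), sprintf("g%02d", 1:60))
  for (i in 1:5) {
    set <- sample(names(stats), 12)
    ours <- preranked_gsea(stats, set, n_perm = 100, seed = i)$es
    ref <- suppressWarnings(
      fgsea::fgseaSimple(list(s = set), stats, nperm = 50, gseaParam = 1, nproc = 1)
    )$ES
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("GSEA sign, reversal and edge-case conventions hold", {
  stats <- setNames(seq(10, 1), paste0("g", 1:10))
  top <- preranked_gsea(stats, paste0("g", 1:3), n_perm = 200, seed = 1)
  expect_gt(top$es, 0)
  # reversing the ranking sends a top set to the bottom and negates the ES
  rev_stats <- setNames(rev(unname(stats)), names(stats))
  bottom <- preranked_gsea(rev_stats, paste0("g", 1:3), n_perm = 200, seed = 1)
  expect_equal(bottom$es, -top$es, tolerance = 1e-12)

  expect_warning(res <- preranked_gsea(stats, "nope", n_perm = 100, seed = 1), "no overlap")
  expect_equal(res$p, 1)
  expect_warning(res <- preranked_gsea(stats, names(stats), n_perm = 100, seed = 1),
                 "entire ranking")
  expect_equal(res$es, 0)
})

test_that("permutation p-values respect the smoothing floor and are seed-reproducible", {
  stats <- setNames(seq(100, 1), paste0("g", 1:100))
  res1 <- preranked_gsea(stats, paste0("g", 1:10), n_perm = 500, seed = 99)
  res2 <- preranked_gsea(stats, paste0("g", 1:10), n_perm = 500, seed = 99)
  expect_identical(res1$p, res2$p)
  expect_identical(res1$nes, res2$nes)
  expect_gte(res1$p, 1 / (500 + 1))
  res3 <- preranked_gsea(stats, paste0("g", 1:10), n_perm = 500, seed = 100)
  expect_gte(res3$p, 1 / 501)
})

test_that("hypergeometric ORA matches exact enumeration on small universes", {
  universe <- paste0("u", 1:20)
  sets <- list(S = universe[1:5])
  res <- ora_enrich(universe[c(1:4, 10)], sets, universe)
  expect_equal(res$p, enum_hyper_p(20, 5, 5, 4), tolerance = 1e-12)
  expect_equal(res$p, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$k, 4L)
  expect_setequal(strsplit(res$overlap_genes, ",")[[1]], universe[1:4])

  # a second configuration on a different small universe
  universe <- paste0("v", 1:12)
  res <- ora_enrich(universe[1:4], list(S = universe[3:8]), universe)
  expect_equal(res$p, enum_hyper_p(12, 6, 4, 2), tolerance = 1e-12)

  # degenerate cases
  res <- ora_enrich(universe[1:3], list(S = universe[10:12]), universe)
  expect_equal(res$p, 1)
  res <- ora_enrich(universe, list(S = universe), universe)
  expect_equal(res$p, 1)  # forced full overlap
  expect_error(ora_enrich(c("x1", "x2"), list(S = universe[1:3]), universe),
               class = "mt_input_error")
})

test_that("ORA FDR equals the literal BH step-up", {
  set.seed(31)
  universe <- paste0("u", 1:200)
  sets <- lapply(setNames(1:20, paste0("S", 1:20)),
                 function(i) sample(universe, sample(5:30, 1)))
  res <- ora_enrich(sample(universe, 25), sets, universe)
  expect_equal(res$fdr, bh_stepup(res$p), tolerance = 1e-12)
})

test_that("benchmarking recovers planted validated targets and applies the minimum", {
  sim <- small_sim()
  sc <- small_scores()
  bm <- benchmark_validated(sc, sim$ledger$catalog, min_targets = 5,
                            n_perm = 300, seed = 17)
  s <- attr(bm, "summary")
  expect_equal(s$n_tested, nrow(bm))
  # planted validated sets sit at the top of each ranking: all enriched
  expect_true(all(bm$es > 0))
  expect_equal(s$n_significant, s$n_tested)

  # a miRNA with fewer validated targets than the minimum is excluded
  few <- sim$ledger$catalog |> dplyr::group_by(mirna) |> dplyr::slice_head(n = 4) |>
    dplyr::ungroup()
  expect_warning(bm2 <- benchmark_validated(sc, few, min_targets = 10, n_perm = 100),
                 "no miRNA")
  expect_equal(nrow(bm2), 0)

  # scrambling the catalog destroys the enrichment
  set.seed(23)
  scram <- sim$ledger$catalog
  scram$gene <- sample(unique(sc$gene), nrow(scram), replace = FALSE)
  bm3 <- benchmark_validated(sc, scram, min_targets = 5, n_perm = 300, seed = 29)
  expect_lt(sum(bm3$significant), max(1, 0.3 * nrow(bm3)))
})

test_that("user-list enrichment finds the generating miRNA and its co-targeting family", {
  sim <- small_sim()
  sc <- small_scores()
  m <- sim$ledger$mirna_profile$mirna[1]
  res <- user_list_mirna_enrichment(extract_top_targets(sc, m, 30), sc, k = 50)
  expect_identical(res$set_name[1], m)
  expect_lt(res$fdr[1], 1e-6)

  # four co-targeting miRNAs sharing 60 % of their targets all surface together
  set.seed(37)
  genes <- sprintf("GENE%04d", 1:400)
  shared <- genes[1:30]
  fam <- sprintf("miR-fam%d", 1:4)
  solo <- "miR-solo"
  calls <- purrr::map_dfr(c(fam, solo), function(m) {
    own <- if (m == solo) sample(genes[201:400], 50) else c(shared, sample(genes[31:200], 20))
    tibble::tibble(algorithm = sample(default_algorithms(), 1), mirna = m,
                   gene = own, call = TRUE)
  })
  fam_bundle <- mt_bundle(predictions = dplyr::distinct(calls), genes = genes,
                          mirnas = c(fam, solo))
  fam_scores <- score_targets(fam_bundle)
  res <- user_list_mirna_enrichment(shared, fam_scores, k = 60, universe = genes)
  expect_true(all(match(fam, res$set_name) <= 4))  # the unrelated miRNA ranks last
  expect_true(all(res$fdr[match(fam, res$set_name)] < 0.05))
})
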