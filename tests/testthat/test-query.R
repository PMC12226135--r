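# A hand-built annotation world with one uniquely qualifying gene: GOOD is
# up-in-tumor, poor-survival, dependent in >= 50 % of 10 entities and
# druggable; the others each fail exactly one criterion.
planted_world <- function() {
  entities <- sprintf("E%02d", 1:10)
  genes <- c("GOOD", "NODRUG", "NODEP", "WRONGDE", "RARE")
  grid <- tidyr::expand_grid(entity = entities, feature = genes)
  de <- grid |>
    dplyr::mutate(
      log2_fold_change = 1, p = 0.001, fdr = 0.001,
      direction = dplyr::case_when(
        feature == "WRONGDE" ~ "down_in_tumor",
        feature == "RARE" & entity %in% entities[1:4] ~ "up_in_tumor",
        feature == "RARE" ~ "ns",
        TRUE ~ "up_in_tumor"
      ),
      undetermined = FALSE
    )
  surv <- grid |>
    dplyr::mutate(cutoff = 5, hazard_ratio = 2.5, logrank_p = 0.001,
                  direction = ifelse(feature == "RARE" & !(entity %in% entities[1:5]),
                                     "ns", "poor_with_high"),
                  undetermined = FALSE)
  dep <- tidyr::expand_grid(entity = entities, gene = genes, screen = c("crispr", "rnai")) |>
    dplyr::mutate(
      fraction_dependent = ifelse(gene == "NODEP", 0.02,
                                  ifelse(entity %in% entities[1:6], 0.3, 0.02)),
      dependent = fraction_dependent >= 0.10,
      essential_fraction = 0
    )
  ann <- mirtev:::new_annotations(de = de, survival = surv, dependency = dep,
                                  druggable = c("GOOD", "NODEP", "WRONGDE", "RARE"))
  scores <- rank_bidirectional(tibble::tibble(
    mirna = "miR-q", gene = genes,
    ectopic = 100, knockout = 100, correlation = 100,
    prediction = c(90, 80, 70, 60, 50),
    n_ectopic_support = 1L, n_ectopic = 1L, n_knockout_support = 1L, n_knockout = 1L,
    n_correlation_support = 1L, n_correlation = 1L,
    n_prediction_support = c(9L, 8L, 7L, 6L, 5L), n_prediction = 10L,
    n_categories = 4L, availability = "EKCP",
    composite = (300 + c(90, 80, 70, 60, 50)) / 4
  ))
  list(scores = scores, ann = ann)
}

test_that("no active criteria returns the full query axis in rank order", {
  w <- planted_world()
  res <- filter_candidates(w$scores, w$ann, "miR-q", query_criteria())
  expect_equal(nrow(res), 5)
  expect_identical(res$candidate[1], "GOOD")
  expect_equal(res$composite, sort(res$composite, decreasing = TRUE))
})

test_that("the full oncogenic-druggable criteria set isolates the planted satisfier", {
  w <- planted_world()
  crit <- criteria_oncogenic_target(dependency_required = TRUE,
                                    druggable_required = TRUE, min_fraction = 0.5)
  res <- filter_candidates(w$scores, w$ann, "miR-q", crit)
  expect_identical(res$candidate, "GOOD")
  expect_equal(res$dependency_pass[1], 6)
  expect_equal(res$de_pass[1], 10)
})

test_that("min_fraction is inclusive at the boundary, against evaluable entities", {
  w <- planted_world()
  # RARE: survival-poor in exactly 5/10 evaluable entities
  crit5 <- query_criteria(survival_filter = "poor_with_high", min_fraction = 0.5)
  expect_true("RARE" %in% filter_candidates(w$scores, w$ann, "miR-q", crit5)$candidate)
  crit6 <- query_criteria(survival_filter = "poor_with_high", min_fraction = 0.6)
  expect_false("RARE" %in% filter_candidates(w$scores, w$ann, "miR-q", crit6)$candidate)
})

test_that("filters compose as intersection and tightening never grows the result", {
  w <- planted_world()
  a <- query_criteria(de_filter = "up_in_tumor", min_fraction = 0.5)
  b <- query_criteria(survival_filter = "poor_with_high", min_fraction = 0.5)
  both <- query_criteria(de_filter = "up_in_tumor", survival_filter = "poor_with_high",
                         min_fraction = 0.5)
  ra <- filter_candidates(w$scores, w$ann, "miR-q", a)$candidate
  rb <- filter_candidates(w$scores, w$ann, "miR-q", b)$candidate
  rboth <- filter_candidates(w$scores, w$ann, "miR-q", both)$candidate
  expect_setequal(rboth, intersect(ra, rb))

  loose <- filter_candidates(w$scores, w$ann, "miR-q",
                             query_criteria(de_filter = "up_in_tumor", min_fraction = 0.3))
  tight <- filter_candidates(w$scores, w$ann, "miR-q",
                             query_criteria(de_filter = "up_in_tumor", min_fraction = 0.9))
  expect_true(all(tight$candidate %in% loose$candidate))

  # every returned candidate re-passes each criterion individually
  res <- filter_candidates(w$scores, w$ann, "miR-q", both)
  expect_true(all(res$de_pass / res$de_evaluable >= 0.5))
  expect_true(all(res$survival_pass / res$survival_evaluable >= 0.5))
})

test_that("entity scope, rank and score cutoffs, and error cases behave", {
  w <- planted_world()
  res <- filter_candidates(w$scores, w$ann, "miR-q",
                           query_criteria(dependency_required = TRUE, entity = "E07"))
  expect_setequal(res$candidate, character(0))  # only entities E01-E06 are dependent
  res <- filter_candidates(w$scores, w$ann, "miR-q",
                           query_criteria(dependency_required = TRUE, entity = "E03"))
  expect_setequal(res$candidate, c("GOOD", "NODRUG", "WRONGDE", "RARE"))

  expect_error(filter_candidates(w$scores, w$ann, "miR-q",
                                 query_criteria(entity = "NOPE")),
               class = "mt_lookup_error")
  expect_error(filter_candidates(w$scores, w$ann, "miR-zz", query_criteria()),
               class = "mt_lookup_error")
  expect_error(query_criteria(min_fraction = 1.5), class = "mt_config_error")
  expect_error(query_criteria(entity = "E01", min_fraction = 0.5),
               class = "mt_config_error")

  res <- filter_candidates(w$scores, w$ann, "miR-q", query_criteria(max_rank = 2))
  expect_equal(nrow(res), 2)
  res <- filter_candidates(w$scores, w$ann, "miR-q",
                           query_criteria(min_score = (300 + 70) / 4))
  expect_equal(nrow(res), 3)
})

test_that("regulators query mirrors the targets query on the other axis", {
  sc <- small_scores()
  g <- sc$gene[1]
  res <- filter_candidates(sc, small_annotations(), g,
                           query_criteria(direction = "regulators_of_mrna"))
  expect_setequal(res$candidate, sc$mirna[sc$gene == g])
  expect_equal(res$rank, sc$mrna_rank[sc$gene == g][match(res$candidate, sc$mirna[sc$gene == g])])
})

test_that("detail reports round-trip the evidence behind a planted pair", {
  sim <- small_sim()
  sc <- small_scores()
  ann <- small_annotations()
  pair <- sim$ledger$planted[1, ]
  rep_ <- detail_report(pair$mirna, pair$gene, sim$bundle, sc, ann)

  row <- sc[sc$mirna == pair$mirna & sc$gene == pair$gene, ]
  expect_equal(rep_$score$composite, row$composite)
  expect_equal(rep_$score$mirna_rank, row$mirna_rank)
  expect_equal(rep_$score$mrna_rank, row$mrna_rank)
  expect_equal(sum(unlist(rep_$prediction_calls)), row$n_prediction_support)

  # panel C reproduces the bundle's per-dataset fold changes exactly
  ect <- sim$bundle$ectopic
  ect <- ect[ect$mirna == pair$mirna & ect$gene == pair$gene, ]
  expect_equal(sort(rep_$ectopic_fold_changes$fold_change), sort(ect$fold_change))
  # planted repression shows up as mostly sub-threshold fold changes
  expect_gt(mean(rep_$ectopic_fold_changes$fold_change < 0.8), 0.5)

  # JSON serialization works
  p <- withr::local_tempfile(fileext = ".json")
  write_report(rep_, p)
  parsed <- jsonlite::read_json(p)
  expect_equal(parsed$score$composite, row$composite)

  # a pair with no knockout data flags the panel instead of failing
  b2 <- sim$bundle
  b2$knockout <- b2$knockout[b2$knockout$gene != pair$gene, ]
  sc2 <- score_targets(b2)
  rep2 <- detail_report(pair$mirna, pair$gene, b2, sc2, ann)
  expect_identical(rep2$knockout_fold_changes, "no data")

  # unscored pairs raise a lookup error that names near misses
  err <- expect_error(detail_report("miR-nope", pair$gene, sim$bundle, sc, ann),
                      class = "mt_lookup_error")
  expect_match(conditionMessage(err), "nearest")
})
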