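# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

small_sim <- function() {
  memo("sim", function() {
    generate_evidence(n_mirnas = 6, n_genes = 300, n_entities = 6, seed = 42)
  })
}

small_scores <- function() {
  memo("scores", function() score_targets(small_sim()$bundle))
}

small_clinical <- function() {
  memo("clinical", function() {
    generate_clinical(small_sim()$ledger, n_tumor = 25, n_normal = 25, n_lines = 15)
  })
}

small_annotations <- function() {
  memo("annotations", function() {
    sim <- small_sim()
    cl <- small_clinical()
    feats <- unique(c(sim$ledger$planted$gene, sim$ledger$mirna_profile$mirna))
    annotate_clinical(cl$expr, cl$samples, cl$depmap, cl$druggable,
                      survival_features = feats)
  })
}

# hand-built four-category bundle with fully known arithmetic
toy_bundle <- function() {
  fc_rows <- function(prefix, mirna, genes, fcs) {
    tibble::tibble(
      dataset_id = rep(sprintf("%s_%s_%d", prefix, mirna, seq_along(fcs[[1]])),
                       times = length(genes)),
      mirna = mirna,
      gene = rep(genes, each = length(fcs[[1]])),
      fold_change = unlist(fcs)
    )
  }
  ect <- dplyr::bind_rows(
    fc_rows("e", "miR-a", c("G1", "G2"), list(c(0.5, 0.7, 0.9), c(1.0, 1.1, 0.95))),
    fc_rows("e", "miR-b", "G1", list(c(0.4, 0.6)))
  )
  ko <- fc_rows("k", "miR-a", c("G1", "G2"), list(c(1.5, 1.3, 1.0, 0.9, 2.0),
                                                  c(1.0, 1.05, 0.8, 1.1, 1.2)))
  cors <- tibble::tibble(
    entity = rep(c("E1", "E2", "E3", "E4"), times = 2),
    mirna = "miR-a",
    gene = rep(c("G1", "G2"), each = 4),
    r = c(-0.5, -0.3, -0.2, 0.1, 0.0, 0.05, -0.05, 0.2)
  )
  preds <- tibble::tibble(
    algorithm = c(default_algorithms()[1:8], default_algorithms()[1]),
    mirna = "miR-a",
    gene = c(rep("G1", 8), "G2"),
    call = TRUE
  )
  mt_bundle(ectopic = ect, knockout = ko, correlations = cors, predictions = preds,
            genes = c("G1", "G2"), mirnas = c("miR-a", "miR-b"))
}

# independent brute-force running-sum oracle (explicit prefix loop)
brute_es <- function(stats, hits) {
  n <- length(stats); nh <- sum(hits)
  wsum <- sum(abs(stats)[hits])
  best <- 0; run <- 0
  for (i in seq_len(n)) {
    run <- run + if (hits[i]) {
      if (wsum > 0) abs(stats[i]) / wsum else 1 / nh
    } else {
      -1 / (n - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# exact hypergeometric tail by enumerating every possible draw
enum_hyper_p <- function(N, K, n, k_obs) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k_obs))
}

# literal Benjamini-Hochberg step-up
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# rank-sum AUC of positives vs negatives
auc_scores <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
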