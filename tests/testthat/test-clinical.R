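make_null_expr <- function(n_genes = 300, n_per_group = 15, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 2 * n_per_group, mean = 5), nrow = n_genes,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              sprintf("s%02d", 1:(2 * n_per_group))))
  list(expr = m, labels = rep(c("tumor", "normal"), each = n_per_group))
}

test_that("differential expression is calibrated under the null and powered under a shift", {
  null <- make_null_expr(seed = 11)
  de <- differential_expression(null$expr, null$labels)
  expect_true(all(abs(de$log2_fold_change) < 1.5))
  expect_lt(abs(mean(de$log2_fold_change)), 0.1)
  # raw p-values approximately uniform
  ks <- suppressWarnings(stats::ks.test(de$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(mean(de$direction != "ns"), 0.02)

  # planted 4-fold (log2FC = 2) shift, n = 20 + 20, small sigma
  set.seed(2)
  m <- matrix(rnorm(200 * 40, mean = 5, sd = 0.5), nrow = 200,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:40)))
  labels <- rep(c("tumor", "normal"), each = 20)
  m[1:10, labels == "tumor"] <- m[1:10, labels == "tumor"] + 2
  de <- differential_expression(m, labels)
  hit <- de[1:10, ]
  expect_true(all(hit$direction == "up_in_tumor"))
  expect_true(all(hit$fdr < 0.05))
  expect_equal(mean(hit$log2_fold_change), 2, tolerance = 0.2)
})

test_that("moderated p equals the closed-form empirical-Bayes formula", {
  # dual-route check: rebuild each gene's two-group statistics with base R,
  # apply the shrinkage formula t = b / (su * s_tilde), s_tilde^2 =
  # (d0*s0^2 + d*s^2) / (d0 + d), p = 2*P[T_{d+d0} > |t|], and compare with
  # the pipeline's reported p
  set.seed(3)
  ng <- 150; npg <- 12
  sds <- exp(rnorm(ng, 0, 0.8))  # heterogeneous true variances
  m <- matrix(rnorm(ng * 2 * npg, mean = 5, sd = rep(sds, 2 * npg)), nrow = ng,
              dimnames = list(sprintf("g%03d", 1:ng), sprintf("s%02d", 1:(2 * npg))))
  labels <- rep(c("tumor", "normal"), each = npg)
  de <- differential_expression(m, labels, use_adjusted_p = FALSE)

  fit <- limma::eBayes(limma::lmFit(m, cbind(1, tumor = as.integer(labels == "tumor"))))
  d0 <- fit$df.prior; s0sq <- fit$s2.prior
  d <- 2 * npg - 2
  su <- sqrt(1 / npg + 1 / npg)
  manual <- vapply(seq_len(ng), function(i) {
    x <- m[i, labels == "tumor"]; y <- m[i, labels == "normal"]
    b <- mean(x) - mean(y)
    s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / d
    s_tilde2 <- (d0 * s0sq + d * s2) / (d0 + d)
    2 * stats::pt(-abs(b / (su * sqrt(s_tilde2))), df = d + d0)
  }, double(1))
  expect_equal(de$p, manual, tolerance = 1e-10)

  # and with the prior switched off, the gene-wise statistic is the classical
  # equal-variance t-test, recovered exactly from the same fit quantities
  ord_manual <- vapply(seq_len(ng), function(i) {
    x <- m[i, labels == "tumor"]; y <- m[i, labels == "normal"]
    s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / d
    2 * stats::pt(-abs((mean(x) - mean(y)) / (su * sqrt(s2))), df = d)
  }, double(1))
  ord_p <- apply(m, 1, function(v) stats::t.test(v[labels == "tumor"], v[labels == "normal"],
                                                 var.equal = TRUE)$p.value)
  expect_equal(ord_manual, unname(ord_p), tolerance = 1e-12)
})

test_that("DE guards and labels behave", {
  null <- make_null_expr(n_genes = 10, n_per_group = 5)
  expect_error(differential_expression(null$expr, rep("tumor", 10)),
               class = "mt_config_error")
  expect_error(differential_expression(null$expr, rep(c("case", "ctrl"), each = 5)),
               class = "mt_config_error")

  # constant or zero-median features are undetermined with absent statistics
  m <- null$expr
  m[1, ] <- 3
  m[2, ] <- c(rep(0, 6), rep(0, 4))
  de <- differential_expression(m, null$labels)
  expect_true(all(de$undetermined[1:2]))
  expect_true(all(is.na(de$p[1:2])))

  # antisymmetry under swapping group labels
  de_fwd <- differential_expression(null$expr, null$labels)
  de_rev <- differential_expression(null$expr,
                                    ifelse(null$labels == "tumor", "normal", "tumor"))
  expect_equal(de_fwd$log2_fold_change, -de_rev$log2_fold_change)
  swap <- c(up_in_tumor = "down_in_tumor", down_in_tumor = "up_in_tumor", ns = "ns")
  expect_identical(unname(swap[de_fwd$direction]), de_rev$direction)
})

test_that("BH FDR is monotone in p and bounded below by p", {
  null <- make_null_expr(seed = 7)
  de <- differential_expression(null$expr, null$labels)
  o <- order(de$p)
  expect_true(all(diff(de$fdr[o]) >= -1e-12))
  expect_true(all(de$fdr >= de$p - 1e-12))
  expect_equal(de$fdr, bh_stepup(de$p), tolerance = 1e-12)
})

test_that("survival association recovers a planted cutoff and direction", {
  cohort <- simulate_survival_cohort(n = 200, hr = 3, cutoff_quantile = 0.5, seed = 9)
  res <- survival_association(cohort$expr, cohort$time, cohort$event)
  expect_false(res$undetermined)
  expect_gt(res$hazard_ratio, 1)
  expect_identical(res$direction, "poor_with_high")
  expect_lt(res$logrank_p, 1e-4)
  # recovered cutoff close to the planted median split
  planted <- attr(cohort, "cutoff")
  srt <- sort(cohort$expr)
  window <- srt[findInterval(planted, srt) + c(-15, 15)]
  expect_gte(res$cutoff, window[1])
  expect_lte(res$cutoff, window[2])
  # and it always lies within the scanned quantile range
  expect_gte(res$cutoff, quantile(cohort$expr, 0.10))
  expect_lte(res$cutoff, quantile(cohort$expr, 0.90))
})

test_that("negating expression mirrors the split exactly and inverts the direction", {
  # high/low at cutoff c on -expr is the complementary split of expr at -c:
  # the log-rank statistic is identical and the hazard ratio inverts
  for (s in c(13, 14, 15)) {
    cohort <- simulate_survival_cohort(n = 151, hr = 4, seed = s)
    fwd <- survival_association(cohort$expr, cohort$time, cohort$event)
    rev <- survival_association(-cohort$expr, cohort$time, cohort$event)
    expect_equal(rev$logrank_p, fwd$logrank_p, tolerance = 1e-9)
    expect_equal(rev$hazard_ratio, 1 / fwd$hazard_ratio, tolerance = 1e-6)
    expect_identical(fwd$direction, "poor_with_high")
    expect_identical(rev$direction, "good_with_high")
  }
})

test_that("degenerate survival inputs are undetermined, not errors", {
  expect_true(survival_association(rep(2, 50), rexp(50), rbinom(50, 1, 0.5))$undetermined)
  expect_true(survival_association(rnorm(50), rexp(50), rep(0L, 50))$undetermined)
  expect_true(survival_association(rnorm(3), rexp(3), c(1L, 0L, 1L))$undetermined)
})

test_that("the selected-cutoff log-rank p is anti-conservative under the null", {
  # exchangeable survival: the maximally selected statistic inflates the naive
  # p-value; documented as a property, deliberately not corrected
  set.seed(17)
  ps <- replicate(120, {
    n <- 60
    res <- survival_association(rnorm(n), rexp(n, 0.01), rbinom(n, 1, 0.8))
    res$logrank_p
  })
  expect_gt(mean(ps < 0.05), 0.05)   # inflated type-I rate
  expect_lt(mean(ps), 0.5)           # stochastically smaller than uniform
})

test_that("dependency flag flips exactly at the 10 % line-fraction, exhaustively to n = 50", {
  for (n in 1:50) {
    for (k in 0:n) {
      effects <- c(rep(-0.6, k), rep(0, n - k))
      call <- dependency_call(effects)
      expect_identical(call$dependent, k / n >= 0.10)
      expect_equal(call$fraction_dependent, k / n)
    }
  }
  # boundary values: exactly -0.5 is not a dependency, strictly below -1 is essential
  call <- dependency_call(c(-0.5, -0.6, -1.0, -1.2), dep_frac = 0.10)
  expect_equal(call$fraction_dependent, 3 / 4)
  expect_equal(call$essential_fraction, 1 / 4)
  expect_error(dependency_call(numeric()), class = "mt_validation_error")
})

test_that("druggability is plain membership with an empty-list warning", {
  expect_true(druggability_flag("DBF4", c("DBF4", "CDC7")))
  expect_false(druggability_flag("ZEB1", c("DBF4", "CDC7")))
  expect_warning(flag <- druggability_flag("DBF4", character()), "empty")
  expect_false(flag)
})

test_that("annotate_clinical assembles consistent per-entity tables", {
  ann <- small_annotations()
  sim <- small_sim()
  expect_s3_class(ann, "mt_annotations")
  expect_setequal(unique(ann$de$entity), sim$ledger$entities)
  expect_setequal(unique(ann$dependency$screen), c("crispr", "rnai"))
  # planted up-in-tumor genes are predominantly recovered as such
  up <- sim$ledger$gene_profile$gene[sim$ledger$gene_profile$de_direction == "up_in_tumor"]
  calls <- ann$de |> dplyr::filter(feature %in% up, !undetermined)
  expect_gt(mean(calls$direction == "up_in_tumor"), 0.8)
  # planted dependent genes are flagged; neutral genes are not
  dep_genes <- sim$ledger$gene_profile$gene[sim$ledger$gene_profile$dependency_fraction > 0]
  dep_calls <- ann$dependency |> dplyr::filter(gene %in% dep_genes)
  expect_gt(mean(dep_calls$dependent), 0.9)
  null_calls <- ann$dependency |> dplyr::filter(!(gene %in% dep_genes))
  expect_lt(mean(null_calls$dependent), 0.05)
})
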