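#' Tumor-vs-normal differential expression
#'
#' Moderated differential expression of each feature (mRNA or miRNA)
#' between tumor and normal samples of one cancer entity, using limma's
#' empirical-Bayes shrinkage of gene-wise variances. Direction labels
#' (`up_in_tumor` / `down_in_tumor` / `ns`) use BH-adjusted p-values at
#' `alpha` by default. Features below the expression floor — constant
#' across samples or with median zero — are reported `undetermined`, with
#' all statistics absent.
#'
#' @param expr Numeric feature x sample matrix on the log2 scale, with row
#'   and column names.
#' @param labels Character/factor per sample: `"tumor"` or `"normal"`.
#' @param entity Cancer-entity code recorded in the result.
#' @param alpha Significance level for direction labels.
#' @param use_adjusted_p Label directions on BH-adjusted (`TRUE`, default)
#'   or raw p-values.
#' @return Tibble `(entity, feature, log2_fold_change, p, fdr, direction,
#'   undetermined)`; `log2_fold_change` is tumor over normal.
#' @export
differential_expression <- function(expr, labels, entity = "NA", alpha = 0.05,
                                    use_adjusted_p = TRUE) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) abort("`expr` needs feature row names", class = "mt_input_error")
  labels <- as.character(labels)
  if (length(labels) != ncol(expr)) {
    abort("`labels` must have one entry per sample column", class = "mt_input_error")
  }
  bad <- setdiff(unique(labels), c("tumor", "normal"))
  if (length(bad) > 0) {
    abort(sprintf("labels must be 'tumor' or 'normal', got: %s", paste(bad, collapse = ", ")),
          class = "mt_config_error")
  }
  n_t <- sum(labels == "tumor"); n_n <- sum(labels == "normal")
  if (n_t < 2 || n_n < 2) {
    abort(sprintf("need >= 2 samples per group (tumor: %d, normal: %d)", n_t, n_n),
          class = "mt_config_error")
  }

  undetermined <- apply(expr, 1, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0 || max(v) == min(v) || median(v) == 0
  })
  testable <- expr[!undetermined, , drop = FALSE]

  res <- tibble(entity = entity, feature = rownames(expr),
                log2_fold_change = NA_real_, p = NA_real_, fdr = NA_real_,
                direction = "ns", undetermined = undetermined)
  if (nrow(testable) > 0) {
    design <- cbind(Intercept = 1, tumor = as.integer(labels == "tumor"))
    fit <- limma::eBayes(limma::lmFit(testable, design))
    tt <- limma::topTable(fit, coef = "tumor", number = Inf, sort.by = "none")
    idx <- match(rownames(testable), res$feature)
    res$log2_fold_change[idx] <- tt$logFC
    res$p[idx] <- tt$P.Value
    res$fdr[idx] <- tt$adj.P.Val
    p_lab <- if (use_adjusted_p) tt$adj.P.Val else tt$P.Value
    res$direction[idx] <- ifelse(p_lab < alpha,
                                 ifelse(tt$logFC > 0, "up_in_tumor", "down_in_tumor"),
                                 "ns")
  }
  res$direction[res$undetermined] <- "ns"
  res
}

#' Survival association with an optimal expression cutoff
#'
#' Splits a cohort into high/low expression at the cutoff that maximizes
#' the standardized log-rank statistic over candidate splits (maximally
#' selected rank statistic, the approach of the survminer tooling):
#' candidates are the unique expression values between the `scan` quantiles
#' that leave at least `min_group_frac` of the cohort in each group. The
#' reported p-value is the naive log-rank p at the selected cutoff — like
#' the tooling it mirrors, it is not corrected for the cutoff search and is
#' therefore anti-conservative under the null. The hazard ratio (high vs
#' low) comes from a univariate Cox fit on the binary indicator.
#'
#' Cohorts with constant expression, no events, or no admissible cutoff are
#' reported `undetermined` (the "could not be determined due to low
#' expression" case).
#'
#' @param expr Numeric expression per sample.
#' @param time Follow-up time (e.g. days).
#' @param event Event indicator, 1 = death/event, 0 = censored.
#' @param entity,feature Codes recorded in the result.
#' @param scan Length-2 quantile range scanned for cutoffs.
#' @param min_group_frac Minimum fraction of samples in each group.
#' @param alpha Significance level for the direction label.
#' @return One-row tibble `(entity, feature, cutoff, hazard_ratio,
#'   logrank_p, direction, undetermined)`; `direction` is
#'   `poor_with_high` when the high-expression group fares worse
#'   (hazard ratio > 1) at `logrank_p < alpha`, `good_with_high` for the
#'   mirror case, `ns` otherwise.
#' @export
survival_association <- function(expr, time, event, entity = "NA", feature = "NA",
                                 scan = c(0.10, 0.90), min_group_frac = 0.10,
                                 alpha = 0.05) {
  stopifnot(length(expr) == length(time), length(time) == length(event))
  keep <- complete.cases(expr, time, event)
  expr <- expr[keep]; time <- time[keep]; event <- event[keep]

  und <- function() tibble(entity = entity, feature = feature, cutoff = NA_real_,
                           hazard_ratio = NA_real_, logrank_p = NA_real_,
                           direction = "ns", undetermined = TRUE)
  if (length(expr) < 4 || sum(event) < 1 || max(expr) == min(expr)) return(und())

  qs <- quantile(expr, scan, names = FALSE, type = 7)
  candidates <- sort(unique(expr))
  candidates <- candidates[candidates >= qs[1] & candidates < qs[2]]
  n <- length(expr)
  min_n <- max(1L, ceiling(min_group_frac * n))
  ok <- vapply(candidates, function(cut) {
    hi <- sum(expr > cut)
    hi >= min_n && (n - hi) >= min_n
  }, logical(1))
  candidates <- candidates[ok]
  if (length(candidates) == 0) return(und())

  surv <- survival::Surv(time, event)
  stat <- vapply(candidates, function(cut) {
    g <- factor(expr > cut, levels = c(FALSE, TRUE))
    sd_ <- tryCatch(survival::survdiff(surv ~ g), error = function(e) NULL)
    if (is.null(sd_)) return(-Inf)
    sd_$chisq
  }, double(1))
  best <- which.max(stat)
  cutoff <- candidates[best]
  chisq <- stat[best]
  if (!is.finite(chisq)) return(und())
  logrank_p <- pchisq(chisq, df = 1, lower.tail = FALSE)

  high <- factor(expr > cutoff, levels = c(FALSE, TRUE), labels = c("low", "high"))
  # monotone-likelihood warnings are expected when the optimal split
  # separates groups perfectly; the HR direction is still meaningful
  hr <- tryCatch(
    suppressWarnings(exp(unname(stats::coef(survival::coxph(surv ~ high))))),
    error = function(e) NA_real_
  )
  direction <- if (!is.na(hr) && logrank_p < alpha) {
    if (hr > 1) "poor_with_high" else "good_with_high"
  } else "ns"

  tibble(entity = entity, feature = feature, cutoff = cutoff,
         hazard_ratio = hr, logrank_p = logrank_p,
         direction = direction, undetermined = FALSE)
}

#' Cancer cell-line dependency call
#'
#' A gene is flagged dependent in a cancer entity when at least `dep_frac`
#' (default 10 %, inclusive) of the entity's cell lines have a gene-effect
#' score strictly below `dep_effect` (default -0.5; lower means more
#' dependent). The fraction of lines below -1 is reported as
#' `essential_fraction`.
#'
#' @param effects Numeric gene-effect values, one per cell line.
#' @param entity Cancer-entity code.
#' @param gene Gene symbol.
#' @param screen `"crispr"` (Chronos) or `"rnai"` (DEMETER2).
#' @param dep_effect Dependency threshold (strict `<`).
#' @param dep_frac Minimum dependent fraction (inclusive `>=`).
#' @param essential_effect Essentiality threshold (strict `<`).
#' @return One-row tibble `(entity, gene, screen, fraction_dependent,
#'   dependent, essential_fraction)`.
#' @examples
#' dependency_call(c(-0.6, rep(0, 9)))$dependent   # 1/10 lines -> TRUE
#' @export
dependency_call <- function(effects, entity = "NA", gene = "NA",
                            screen = c("crispr", "rnai"),
                            dep_effect = -0.5, dep_frac = 0.10,
                            essential_effect = -1) {
  screen <- match.arg(screen)
  effects <- as.double(effects)
  effects <- effects[!is.na(effects)]
  if (length(effects) == 0) {
    abort("dependency_call needs at least one cell line", class = "mt_validation_error")
  }
  fraction <- sum(effects < dep_effect) / length(effects)
  tibble(entity = entity, gene = gene, screen = screen,
         fraction_dependent = fraction,
         dependent = fraction >= dep_frac,
         essential_fraction = sum(effects < essential_effect) / length(effects))
}

#' Druggability flag
#'
#' Simple case-insensitive membership in a curated druggable-gene list.
#'
#' @param gene Gene symbol(s).
#' @param druggable_set Character vector of druggable gene symbols.
#' @return Logical vector.
#' @export
druggability_flag <- function(gene, druggable_set) {
  if (length(druggable_set) == 0) {
    warn("druggable gene list is empty; every gene flags FALSE")
    return(rep(FALSE, length(gene)))
  }
  tolower(gene) %in% tolower(druggable_set)
}

#' Build the full clinical annotation set
#'
#' Runs [differential_expression()] and [survival_association()] per entity
#' over a clinical table set and [dependency_call()] over a gene-effect
#' table, collecting everything into one `mt_annotations` object.
#'
#' @param expr Named list of feature x sample matrices, one per entity
#'   (log2 scale), or a single matrix with `samples$entity` distinguishing
#'   entities.
#' @param samples Tibble `(sample, entity, group, time, event)`: `group` is
#'   `"tumor"`/`"normal"`; `time`/`event` may be `NA` for normal samples.
#' @param depmap Tibble `(entity, cell_line, gene, effect, screen)` of
#'   gene-effect values.
#' @param druggable Character vector of druggable gene symbols.
#' @param config An [mt_config()].
#' @param survival_features Optional character vector restricting which
#'   features get survival scans (the scan is the expensive step).
#' @return An `mt_annotations` list: tibbles `de`, `survival`, `dependency`
#'   plus the `druggable` vector.
#' @export
annotate_clinical <- function(expr, samples, depmap = NULL, druggable = character(),
                              config = mt_config(), survival_features = NULL) {
  if (is.matrix(expr)) {
    entities <- unique(samples$entity)
    expr <- lapply(setNames(entities, entities), function(ent) {
      expr[, samples$sample[samples$entity == ent], drop = FALSE]
    })
  }
  need_columns(samples, c("sample", "entity", "group"), "sample table")

  de <- purrr::map_dfr(names(expr), function(ent) {
    m <- expr[[ent]]
    s <- samples |> filter(.data$entity == ent)
    s <- s[match(colnames(m), s$sample), ]
    if (sum(s$group == "normal") < 2 || sum(s$group == "tumor") < 2) {
      return(tibble(entity = ent, feature = rownames(m),
                    log2_fold_change = NA_real_, p = NA_real_, fdr = NA_real_,
                    direction = "ns", undetermined = TRUE))
    }
    differential_expression(m, s$group, entity = ent, alpha = config$alpha,
                            use_adjusted_p = config$use_adjusted_p)
  })

  surv <- purrr::map_dfr(names(expr), function(ent) {
    m <- expr[[ent]]
    s <- samples |> filter(.data$entity == ent)
    s <- s[match(colnames(m), s$sample), ]
    tumor <- which(s$group == "tumor" & !is.na(s$time) & !is.na(s$event))
    feats <- rownames(m)
    if (!is.null(survival_features)) feats <- intersect(feats, survival_features)
    purrr::map_dfr(feats, function(f) {
      raw <- survival_association(m[f, tumor], s$time[tumor], s$event[tumor],
                                  entity = ent, feature = f, alpha = config$alpha)
      raw
    })
  })
  # direction labels optionally on BH-adjusted p across features within entity
  if (isTRUE(config$use_adjusted_p) && nrow(surv) > 0) {
    surv <- surv |>
      group_by(.data$entity) |>
      mutate(fdr = ifelse(is.na(.data$logrank_p), NA_real_, p.adjust(.data$logrank_p, "BH")),
             direction = ifelse(!.data$undetermined & !is.na(.data$fdr) & .data$fdr < config$alpha,
                                ifelse(.data$hazard_ratio > 1, "poor_with_high", "good_with_high"),
                                "ns")) |>
      ungroup() |>
      select(-"fdr")
  }

  dependency <- if (is.null(depmap) || nrow(depmap) == 0) {
    tibble(entity = character(), gene = character(), screen = character(),
           fraction_dependent = double(), dependent = logical(),
           essential_fraction = double())
  } else {
    need_columns(depmap, c("entity", "cell_line", "gene", "effect", "screen"), "gene-effect table")
    depmap |>
      group_by(.data$entity, .data$gene, .data$screen) |>
      summarise(
        fraction_dependent = sum(.data$effect < config$dep_effect) / n(),
        dependent = .data$fraction_dependent >= config$dep_frac,
        essential_fraction = sum(.data$effect < -1) / n(),
        .groups = "drop"
      ) |>
      select("entity", "gene", "screen", "fraction_dependent", "dependent",
             "essential_fraction")
  }

  new_annotations(de = de, survival = surv, dependency = dependency,
                  druggable = normalize_ids(druggable, axis = "gene"))
}
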