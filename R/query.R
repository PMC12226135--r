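#' Candidate-query criteria
#'
#' Bundles the cancer-relevance filters a candidate must satisfy. Entity
#' scope is either one entity code or "in at least `min_fraction` of cancer
#' types"; fractions are judged against the entities with evaluable data
#' for that criterion (differential expression, for instance, exists only
#' for entities with normal-tissue profiles), inclusive at the boundary.
#' When neither is given, a criterion passes if it holds in at least one
#' entity.
#'
#' @param direction `"targets_of_mirna"` (rank genes for a miRNA) or
#'   `"regulators_of_mrna"` (rank miRNAs for a gene).
#' @param survival_filter Optional: require `"poor_with_high"` or
#'   `"good_with_high"` survival association.
#' @param de_filter Optional: require `"up_in_tumor"` or `"down_in_tumor"`.
#' @param dependency_required Require a cell-line dependency flag.
#' @param druggable_required Require membership in the druggable list.
#' @param entity Restrict scope to one entity code.
#' @param min_fraction Minimum fraction of evaluable entities, in (0, 1].
#' @param max_rank Optional cap on the query-axis rank.
#' @param min_score Optional floor on the composite score.
#' @param dependency_rule `"either"` screen suffices (default) or `"both"`.
#' @return A list with class `mt_criteria`.
#' @export
query_criteria <- function(direction = c("targets_of_mirna", "regulators_of_mrna"),
                           survival_filter = NULL, de_filter = NULL,
                           dependency_required = FALSE, druggable_required = FALSE,
                           entity = NULL, min_fraction = NULL,
                           max_rank = NULL, min_score = NULL,
                           dependency_rule = c("either", "both")) {
  direction <- match.arg(direction)
  dependency_rule <- match.arg(dependency_rule)
  if (!is.null(survival_filter)) {
    survival_filter <- match.arg(survival_filter, c("poor_with_high", "good_with_high"))
  }
  if (!is.null(de_filter)) {
    de_filter <- match.arg(de_filter, c("up_in_tumor", "down_in_tumor"))
  }
  if (!is.null(entity) && !is.null(min_fraction)) {
    abort("give either a single `entity` or `min_fraction`, not both",
          class = "mt_config_error")
  }
  if (!is.null(min_fraction) && !(min_fraction > 0 && min_fraction <= 1)) {
    abort("`min_fraction` must lie in (0, 1]", class = "mt_config_error")
  }
  structure(list(direction = direction, survival_filter = survival_filter,
                 de_filter = de_filter, dependency_required = dependency_required,
                 druggable_required = druggable_required, entity = entity,
                 min_fraction = min_fraction, max_rank = max_rank,
                 min_score = min_score, dependency_rule = dependency_rule),
            class = "mt_criteria")
}

#' Convenience presets
#'
#' `criteria_oncogenic_target()` is the worked setting for finding druggable
#' oncogenic targets of a tumor-suppressive miRNA: targets up in tumors and
#' associated with poor survival with high expression.
#' `criteria_suppressive_target()` is the mirror.
#'
#' @param ... Further arguments passed to [query_criteria()].
#' @return An `mt_criteria` list.
#' @export
criteria_oncogenic_target <- function(...) {
  query_criteria(survival_filter = "poor_with_high", de_filter = "up_in_tumor", ...)
}

#' @rdname criteria_oncogenic_target
#' @export
criteria_suppressive_target <- function(...) {
  query_criteria(survival_filter = "good_with_high", de_filter = "down_in_tumor", ...)
}

#' Filter ranked candidates by cancer criteria
#'
#' Starting from one query axis (all scored targets of a miRNA, or all
#' scored miRNA regulators of a gene), keeps the candidates that satisfy
#' every active criterion and returns them ordered by composite score, each
#' row carrying per-criterion pass counts such as "poor-survival in 12/32
#' evaluable entities". Filters compose as set intersection, so tightening
#' any cutoff can only shrink the result; contradictory criteria simply
#' yield an empty (valid) result.
#'
#' @param scores An `mt_scores` table.
#' @param annotations An `mt_annotations` object.
#' @param id The query identifier: a miRNA for `targets_of_mirna`, a gene
#'   for `regulators_of_mrna`.
#' @param criteria An [query_criteria()] list.
#' @return Tibble of passing candidates ordered by descending composite,
#'   with columns `candidate`, `composite`, `rank`, and per-criterion
#'   `*_pass` / `*_evaluable` counts plus `druggable`.
#' @export
filter_candidates <- function(scores, annotations, id,
                              criteria = query_criteria()) {
  stopifnot(inherits(criteria, "mt_criteria"), inherits(annotations, "mt_annotations"))
  targets_mode <- criteria$direction == "targets_of_mirna"
  axis_col <- if (targets_mode) "mirna" else "gene"
  cand_col <- if (targets_mode) "gene" else "mirna"
  rank_col <- if (targets_mode) "mirna_rank" else "mrna_rank"

  rows <- scores[tolower(scores[[axis_col]]) == tolower(id), ]
  if (nrow(rows) == 0) {
    abort(sprintf("'%s' is not a scored %s", id,
                  if (targets_mode) "miRNA" else "gene"), class = "mt_lookup_error")
  }
  check_entity_known(criteria, annotations)

  out <- tibble(candidate = rows[[cand_col]],
                composite = rows$composite,
                rank = rows[[rank_col]])

  surv <- criterion_counts(annotations$survival, out$candidate, "feature",
                           function(d) d$direction == (criteria$survival_filter %||% "poor_with_high"),
                           evaluable = function(d) !d$undetermined,
                           entity = criteria$entity)
  de <- criterion_counts(annotations$de, out$candidate, "feature",
                         function(d) d$direction == (criteria$de_filter %||% "up_in_tumor"),
                         evaluable = function(d) !d$undetermined,
                         entity = criteria$entity)
  dep_tbl <- annotations$dependency |>
    group_by(.data$entity, .data$gene) |>
    summarise(dep = if (criteria$dependency_rule == "either") any(.data$dependent)
              else all(.data$dependent) && n() > 1,
              .groups = "drop")
  dep <- criterion_counts(dep_tbl, out$candidate, "gene",
                          function(d) d$dep, evaluable = function(d) rep(TRUE, nrow(d)),
                          entity = criteria$entity)

  out$survival_pass <- surv$pass; out$survival_evaluable <- surv$evaluable
  out$de_pass <- de$pass; out$de_evaluable <- de$evaluable
  out$dependency_pass <- dep$pass; out$dependency_evaluable <- dep$evaluable
  out$druggable <- druggability_flag_quiet(out$candidate, annotations$druggable)

  keep <- rep(TRUE, nrow(out))
  scope_ok <- function(pass, evaluable) {
    if (!is.null(criteria$entity)) pass >= 1
    else if (!is.null(criteria$min_fraction)) {
      evaluable > 0 & (pass / pmax(evaluable, 1)) >= criteria$min_fraction
    } else pass >= 1
  }
  if (!is.null(criteria$survival_filter)) {
    keep <- keep & scope_ok(out$survival_pass, out$survival_evaluable)
  }
  if (!is.null(criteria$de_filter)) keep <- keep & scope_ok(out$de_pass, out$de_evaluable)
  if (isTRUE(criteria$dependency_required)) {
    keep <- keep & scope_ok(out$dependency_pass, out$dependency_evaluable)
  }
  if (isTRUE(criteria$druggable_required)) keep <- keep & out$druggable
  if (!is.null(criteria$max_rank)) keep <- keep & out$rank <= criteria$max_rank
  if (!is.null(criteria$min_score)) keep <- keep & out$composite >= criteria$min_score

  out[keep, ] |> arrange(desc(.data$composite), .data$candidate)
}

check_entity_known <- function(criteria, annotations) {
  if (is.null(criteria$entity)) return(invisible())
  known <- unique(c(annotations$de$entity, annotations$survival$entity,
                    annotations$dependency$entity))
  if (!criteria$entity %in% known) {
    abort(sprintf("entity '%s' has no annotations (known: %s)", criteria$entity,
                  paste(head(sort(known), 10), collapse = ", ")),
          class = "mt_lookup_error")
  }
  invisible()
}

criterion_counts <- function(tbl, candidates, key, pass_fn, evaluable, entity = NULL) {
  if (!is.null(entity)) tbl <- tbl[tbl$entity == entity, , drop = FALSE]
  if (nrow(tbl) == 0) {
    return(list(pass = rep(0L, length(candidates)), evaluable = rep(0L, length(candidates))))
  }
  tbl$..eval <- evaluable(tbl)
  tbl$..pass <- tbl$..eval & pass_fn(tbl)
  agg <- tbl |>
    mutate(..key = tolower(.data[[key]])) |>
    group_by(.data$..key) |>
    summarise(pass = sum(.data$..pass, na.rm = TRUE),
              evaluable = sum(.data$..eval, na.rm = TRUE), .groups = "drop")
  m <- match(tolower(candidates), agg$..key)
  list(pass = ifelse(is.na(m), 0L, agg$pass[m]),
       evaluable = ifelse(is.na(m), 0L, agg$evaluable[m]))
}

druggability_flag_quiet <- function(gene, druggable_set) {
  if (length(druggable_set) == 0) return(rep(FALSE, length(gene)))
  tolower(gene) %in% tolower(druggable_set)
}

#' Per-pair detail report
#'
#' Assembles everything known about one miRNA-gene pair into a structured
#' report: the composite score with both ranks; per-algorithm prediction
#' calls; per-dataset ectopic and knockout fold changes; per-entity
#' correlations; per-entity differential expression of the miRNA and of the
#' gene; their survival associations; and the gene's dependency calls.
#' Categories without data are marked `"no data"`. The report is a plain
#' list serializable as JSON via [write_report()].
#'
#' @param mirna,gene The pair identifiers (case-insensitive). The pair must
#'   be present in the score table.
#' @param bundle The [mt_bundle()] the scores came from.
#' @param scores An `mt_scores` table.
#' @param annotations An `mt_annotations` object.
#' @return A list with class `mt_report`.
#' @export
detail_report <- function(mirna, gene, bundle, scores, annotations) {
  stopifnot(inherits(bundle, "mt_bundle"), inherits(annotations, "mt_annotations"))
  hit <- which(tolower(scores$mirna) == tolower(mirna) &
                 tolower(scores$gene) == tolower(gene))
  if (length(hit) == 0) {
    near_m <- nearest_ids(mirna, unique(scores$mirna))
    near_g <- nearest_ids(gene, unique(scores$gene))
    abort(sprintf(
      "pair (%s, %s) is not scored; nearest miRNAs: %s; nearest genes: %s",
      mirna, gene, paste(near_m, collapse = ", "), paste(near_g, collapse = ", ")
    ), class = "mt_lookup_error")
  }
  row <- scores[hit[1], ]
  mirna <- row$mirna; gene <- row$gene

  pair_rows <- function(tbl) {
    tbl[tolower(tbl$mirna) == tolower(mirna) & tolower(tbl$gene) == tolower(gene), ,
        drop = FALSE]
  }
  feat_rows <- function(tbl, feature) {
    tbl[tolower(tbl$feature) == tolower(feature), , drop = FALSE]
  }
  or_no_data <- function(tbl) if (nrow(tbl) == 0) "no data" else tbl

  preds <- pair_rows(bundle$predictions)
  calls <- setNames(rep(FALSE, length(bundle$algorithms)), bundle$algorithms)
  calls[preds$algorithm[preds$call]] <- TRUE

  report <- list(
    pair = list(mirna = mirna, gene = gene),
    score = list(composite = row$composite, availability = row$availability,
                 partials = list(ectopic = row$ectopic, knockout = row$knockout,
                                 correlation = row$correlation, prediction = row$prediction),
                 mirna_rank = row$mirna_rank, mrna_rank = row$mrna_rank),
    prediction_calls = as.list(calls),
    ectopic_fold_changes = or_no_data(pair_rows(bundle$ectopic)[c("dataset_id", "fold_change")]),
    knockout_fold_changes = or_no_data(pair_rows(bundle$knockout)[c("dataset_id", "fold_change")]),
    correlations = or_no_data(pair_rows(bundle$correlations)[c("entity", "r")]),
    mirna_differential_expression = or_no_data(feat_rows(annotations$de, mirna)),
    gene_differential_expression = or_no_data(feat_rows(annotations$de, gene)),
    mirna_survival = or_no_data(feat_rows(annotations$survival, mirna)),
    gene_survival = or_no_data(feat_rows(annotations$survival, gene)),
    gene_dependency = or_no_data(
      annotations$dependency[tolower(annotations$dependency$gene) == tolower(gene), ,
                             drop = FALSE]),
    gene_druggable = druggability_flag_quiet(gene, annotations$druggable)
  )
  structure(report, class = "mt_report")
}

nearest_ids <- function(id, pool, n = 3) {
  if (length(pool) == 0) return("none")
  d <- utils::adist(tolower(id), tolower(pool))[1, ]
  pool[order(d)][seq_len(min(n, length(pool)))]
}

#' @rdname detail_report
#' @param report An `mt_report`.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "mt_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @export
print.mt_report <- function(x, ...) {
  cat(sprintf("<mt_report> %s -> %s\n", x$pair$mirna, x$pair$gene))
  cat(sprintf("  composite %.4g (mask %s), miRNA-rank %d, mRNA-rank %d\n",
              x$score$composite, x$score$availability,
              x$score$mirna_rank, x$score$mrna_rank))
  cat(sprintf("  prediction calls: %d/%d\n", sum(unlist(x$prediction_calls)),
              length(x$prediction_calls)))
  for (k in c("ectopic_fold_changes", "knockout_fold_changes", "correlations")) {
    v <- x[[k]]
    cat(sprintf("  %s: %s\n", k, if (identical(v, "no data")) "no data"
                else sprintf("%d records", nrow(v))))
  }
  invisible(x)
}
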