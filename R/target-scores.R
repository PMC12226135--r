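#' Extract a miRNA's top-ranked targets
#'
#' Returns the first `k` genes by `mirna_rank` (1 = best composite score)
#' for one miRNA; when fewer than `k` genes are scored, all of them are
#' returned with a shortfall warning.
#'
#' @param scores An `mt_scores` table.
#' @param mirna One miRNA identifier (case-insensitive).
#' @param k Top-set size (default 1000).
#' @return Character vector of gene symbols ordered by rank.
#' @export
extract_top_targets <- function(scores, mirna, k = 1000) {
  stopifnot(k >= 1)
  rows <- scores |> filter(tolower(.data$mirna) == tolower(.env$mirna))
  if (nrow(rows) == 0) {
    near <- head(unique(scores$mirna), 5)
    abort(sprintf("miRNA '%s' is not in the score table (known miRNAs include: %s)",
                  mirna, paste(near, collapse = ", ")), class = "mt_lookup_error")
  }
  rows <- rows |> arrange(.data$mirna_rank)
  if (nrow(rows) < k) {
    warn(sprintf("miRNA '%s' has only %d scored targets (< top-%d)", mirna, nrow(rows), k))
  }
  head(rows$gene, k)
}

#' Clinical summary scores over a miRNA's top targets
#'
#' Each of a miRNA's top-`k` targets contributes +1 / -1 / 0 and the
#' summary score is their sum over the fixed-size top set:
#'
#' * tumor/normal score — +1 per target significantly up in tumors, -1 per
#'   target significantly down; a high score means the miRNA's targets are
#'   predominantly overexpressed in tumors (the pattern expected for
#'   targets of tumor-suppressive miRNAs).
#' * overall-survival score — +1 per target significantly associated with
#'   poor survival (high expression, hazard ratio > 1), -1 for good
#'   survival.
#'
#' Targets with no or undetermined annotation for an entity contribute 0,
#' keeping scores comparable across miRNAs.
#'
#' @param top_set Character vector of gene symbols (order irrelevant).
#' @param de DE results for one entity (tibble from
#'   [differential_expression()]).
#' @param survival Survival associations for one entity.
#' @param mirna,entity Codes recorded in the result.
#' @return One-row tibble `(mirna, entity, kind, score, n_plus, n_minus,
#'   top_set_size)`.
#' @export
tumor_normal_target_score <- function(top_set, de, mirna = "NA", entity = "NA") {
  signed_target_score(top_set, de, key = "feature",
                      plus = "up_in_tumor", minus = "down_in_tumor",
                      kind = "tumor_normal", mirna = mirna, entity = entity)
}

#' @rdname tumor_normal_target_score
#' @export
overall_survival_target_score <- function(top_set, survival, mirna = "NA", entity = "NA") {
  signed_target_score(top_set, survival, key = "feature",
                      plus = "poor_with_high", minus = "good_with_high",
                      kind = "overall_survival", mirna = mirna, entity = entity)
}

signed_target_score <- function(top_set, ann, key, plus, minus, kind, mirna, entity) {
  if (nrow(ann) == 0) {
    abort(sprintf("no %s annotations supplied for entity '%s'",
                  kind, entity), class = "mt_lookup_error")
  }
  dirs <- ann$direction[match(tolower(top_set), tolower(ann[[key]]))]
  n_plus <- sum(dirs == plus, na.rm = TRUE)
  n_minus <- sum(dirs == minus, na.rm = TRUE)
  tibble(mirna = mirna, entity = entity, kind = kind,
         score = n_plus - n_minus, n_plus = n_plus, n_minus = n_minus,
         top_set_size = length(top_set))
}

#' Per-miRNA clinical summary scores across all entities
#'
#' Computes both summary-score kinds for every miRNA in the score table
#' against every entity in the annotations, and attaches the miRNA's own
#' DE / survival class (from its own annotation records) for grouping
#' miRNAs into tumor-suppressive-like vs oncomiR-like sets.
#'
#' @param scores An `mt_scores` table.
#' @param annotations An `mt_annotations` object covering the targets (and
#'   ideally the miRNAs themselves).
#' @param k Top-set size.
#' @return A tibble with class `mt_summary_scores`: one row per
#'   (miRNA, entity, kind), columns as in [tumor_normal_target_score()]
#'   plus `mirna_direction` (the miRNA's own DE or survival call in that
#'   entity, `NA` when unannotated).
#' @export
target_summary_scores <- function(scores, annotations, k = 1000) {
  stopifnot(inherits(annotations, "mt_annotations"))
  mirnas <- unique(scores$mirna)
  tops <- lapply(setNames(mirnas, mirnas), function(m) {
    suppressWarnings(extract_top_targets(scores, m, k))
  })

  de_entities <- unique(annotations$de$entity)
  surv_entities <- unique(annotations$survival$entity)

  de_part <- purrr::map_dfr(de_entities, function(ent) {
    ann <- annotations$de |> filter(.data$entity == ent)
    purrr::map_dfr(mirnas, function(m) {
      row <- tumor_normal_target_score(tops[[m]], ann, mirna = m, entity = ent)
      row$mirna_direction <- dir_lookup(ann, m)
      row
    })
  })
  surv_part <- purrr::map_dfr(surv_entities, function(ent) {
    ann <- annotations$survival |> filter(.data$entity == ent)
    purrr::map_dfr(mirnas, function(m) {
      row <- overall_survival_target_score(tops[[m]], ann, mirna = m, entity = ent)
      row$mirna_direction <- dir_lookup(ann, m)
      row
    })
  })
  out <- bind_rows(de_part, surv_part)
  class(out) <- unique(c("mt_summary_scores", class(out)))
  out
}

dir_lookup <- function(ann, feature) {
  hit <- match(tolower(feature), tolower(ann$feature))
  if (is.na(hit)) NA_character_ else ann$direction[hit]
}
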