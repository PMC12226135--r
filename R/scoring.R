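#' Partial evidence scores
#'
#' Each evidence category contributes a partial score equal to 100 times the
#' fraction of its datasets that support the miRNA-target relationship:
#'
#' * ectopic expression: fold change strictly below `threshold` (default 0.8,
#'   i.e. repression by more than 1.25-fold);
#' * knockout/knockdown: fold change strictly above `threshold` (default
#'   1.25);
#' * tumor correlation: Pearson coefficient strictly below `threshold`
#'   (default -0.1);
#' * prediction algorithms: positive calls over the fixed algorithm
#'   complement (so one call among ten tools scores 10, and a pair no tool
#'   reports scores 0, never `NA`).
#'
#' The maximum possible partial score for every category is 100. Categories
#' with no datasets for a pair return `NA` ("no data"), which is distinct
#' from a 0 ("contradicting data") — except for the prediction partial,
#' whose denominator is the configured complement and therefore always
#' defined.
#'
#' @param fold_changes Positive linear fold changes (treated / control), one
#'   per dataset.
#' @param rs Pearson correlation coefficients in `[-1, 1]`, one per entity.
#' @param calls Logical vector of positive prediction calls; its length must
#'   not exceed `n_algorithms`.
#' @param threshold Category cutoff; strict comparison in every category.
#' @param n_algorithms Size of the algorithm complement (denominator).
#' @return A score in `[0, 100]`, or `NA` when the category is empty.
#' @examples
#' partial_ectopic(c(0.5, 0.7, 0.9))   # 2 of 3 repressed -> 66.67
#' partial_knockout(c(1.5, 1.3, 1.0, 0.9, 2.0))  # 3 of 5 induced -> 60
#' partial_prediction(rep(TRUE, 8), n_algorithms = 10)  # -> 80
#' @export
partial_ectopic <- function(fold_changes, threshold = 0.8) {
  fold_changes <- check_fc(fold_changes)
  if (length(fold_changes) == 0) return(NA_real_)
  100 * sum(fold_changes < threshold) / length(fold_changes)
}

#' @rdname partial_ectopic
#' @export
partial_knockout <- function(fold_changes, threshold = 1.25) {
  fold_changes <- check_fc(fold_changes)
  if (length(fold_changes) == 0) return(NA_real_)
  100 * sum(fold_changes > threshold) / length(fold_changes)
}

#' @rdname partial_ectopic
#' @export
partial_correlation <- function(rs, threshold = -0.1) {
  rs <- as.double(rs)
  rs <- rs[!is.na(rs)]
  if (any(abs(rs) > 1)) {
    abort("correlation coefficients must satisfy |r| <= 1", class = "mt_validation_error")
  }
  if (length(rs) == 0) return(NA_real_)
  100 * sum(rs < threshold) / length(rs)
}

#' @rdname partial_ectopic
#' @export
partial_prediction <- function(calls, n_algorithms = 10) {
  if (n_algorithms < 1) {
    abort("the algorithm complement must contain at least one tool",
          class = "mt_config_error")
  }
  calls <- as.logical(calls)
  if (length(calls) > n_algorithms) {
    abort(sprintf("%d calls exceed the configured complement of %d algorithms",
                  length(calls), n_algorithms), class = "mt_validation_error")
  }
  100 * sum(calls, na.rm = TRUE) / n_algorithms
}

check_fc <- function(fold_changes) {
  fold_changes <- as.double(fold_changes)
  fold_changes <- fold_changes[!is.na(fold_changes)]
  if (any(fold_changes <= 0)) {
    abort("fold changes must be positive (linear scale, treated / control)",
          class = "mt_validation_error")
  }
  fold_changes
}

#' Composite target prediction score
#'
#' The composite score is the equally weighted mean of the partial scores of
#' the categories that have data: the sum of present partials divided by the
#' number of present categories. With all four categories this is the
#' sum-divided-by-4 rule that fixes the ceiling at 100; for miRNAs with no
#' ectopic and no knockout datasets it reduces to the
#' (correlation + prediction) / 2 fallback. Pairs with no data in any
#' category are unscorable and return `NA`.
#'
#' @param ectopic,knockout,correlation,prediction Partial scores in
#'   `[0, 100]`, or `NA` when the category has no data for the pair.
#' @return The composite score in `[0, 100]`, or `NA` if every category is
#'   absent.
#' @examples
#' composite_score(100, 60, 90.625, 80)   # 82.65625
#' composite_score(NA, NA, 90, 70)        # fallback: (90 + 70) / 2 = 80
#' @export
composite_score <- function(ectopic, knockout, correlation, prediction) {
  parts <- c(ectopic, knockout, correlation, prediction)
  if (length(parts) != 4) {
    abort("supply exactly one value per category (use NA for absent categories)",
          class = "mt_validation_error")
  }
  present <- !is.na(parts)
  if (!any(present)) return(NA_real_)
  if (any(parts[present] < 0 | parts[present] > 100)) {
    abort("partial scores must lie in [0, 100]", class = "mt_validation_error")
  }
  sum(parts[present]) / sum(present)
}

#' Score every evidenced miRNA-gene pair in a bundle
#'
#' Builds the full score table: for every pair with data in at least one
#' category (a measured fold change, a measured correlation, or a positive
#' prediction call), computes the four partial scores, the composite, the
#' availability mask and both directional ranks. Pairs with no evidence in
#' any category are omitted rather than scored zero, so "never measured"
#' stays distinct from "measured and unsupported".
#'
#' @param bundle An [mt_bundle()].
#' @param config An [mt_config()]; thresholds and the algorithm complement
#'   are taken from it.
#' @return A tibble with class `mt_scores`, one row per scored pair, ordered
#'   by miRNA then descending composite. Columns: identifiers, the four
#'   partials with their `(support, total)` counts, `composite`,
#'   `n_categories`, `availability` (subset of `"EKCP"`), `mirna_rank`,
#'   `mrna_rank`.
#' @export
score_targets <- function(bundle, config = mt_config()) {
  stopifnot(inherits(bundle, "mt_bundle"))
  validate_config(config)

  ect <- bundle$ectopic |>
    group_by(.data$mirna, .data$gene) |>
    summarise(n_ectopic_support = sum(.data$fold_change < config$fc_down),
              n_ectopic = n(), .groups = "drop")
  ko <- bundle$knockout |>
    group_by(.data$mirna, .data$gene) |>
    summarise(n_knockout_support = sum(.data$fold_change > config$fc_up),
              n_knockout = n(), .groups = "drop")
  cors <- bundle$correlations |>
    group_by(.data$mirna, .data$gene) |>
    summarise(n_correlation_support = sum(.data$r < config$r_cut),
              n_correlation = n(), .groups = "drop")
  n_algos <- length(config$algorithms)
  extra <- setdiff(unique(bundle$predictions$algorithm), config$algorithms)
  if (length(extra) > 0) {
    abort(sprintf("prediction calls from algorithm(s) outside the configured complement: %s",
                  paste(head(extra, 5), collapse = ", ")), class = "mt_validation_error")
  }
  preds <- bundle$predictions |>
    filter(.data$call) |>
    group_by(.data$mirna, .data$gene) |>
    summarise(n_prediction_support = n(), .groups = "drop")

  scores <- full_join(ect, ko, by = c("mirna", "gene")) |>
    full_join(cors, by = c("mirna", "gene")) |>
    full_join(preds, by = c("mirna", "gene")) |>
    mutate(
      across(starts_with("n_"), ~ as.integer(tidyr::replace_na(.x, 0L))),
      n_prediction = as.integer(n_algos),
      ectopic = ifelse(.data$n_ectopic > 0, 100 * .data$n_ectopic_support / .data$n_ectopic, NA_real_),
      knockout = ifelse(.data$n_knockout > 0, 100 * .data$n_knockout_support / .data$n_knockout, NA_real_),
      correlation = ifelse(.data$n_correlation > 0,
                           100 * .data$n_correlation_support / .data$n_correlation, NA_real_),
      prediction = 100 * .data$n_prediction_support / n_algos,
      n_categories = (!is.na(.data$ectopic)) + (!is.na(.data$knockout)) +
        (!is.na(.data$correlation)) + 1L,
      composite = (tidyr::replace_na(.data$ectopic, 0) + tidyr::replace_na(.data$knockout, 0) +
                     tidyr::replace_na(.data$correlation, 0) + .data$prediction) / .data$n_categories,
      availability = paste0(ifelse(is.na(.data$ectopic), "", "E"),
                            ifelse(is.na(.data$knockout), "", "K"),
                            ifelse(is.na(.data$correlation), "", "C"), "P")
    )

  rank_bidirectional(new_scores(scores[score_table_cols_pre_rank()]))
}

score_table_cols_pre_rank <- function() setdiff(score_table_cols, c("mirna_rank", "mrna_rank"))

#' Assign bidirectional ranks
#'
#' Within each miRNA, genes are ranked 1..N by descending composite score
#' (`mirna_rank`: rank of the gene among the miRNA's potential targets);
#' within each gene, miRNAs are ranked likewise (`mrna_rank`: rank of the
#' miRNA among the gene's potential regulators). Ties are broken by the
#' lexicographically smaller identifier, so ranks are a bijection onto
#' 1..N and invariant to input row order.
#'
#' @param scores A score table with composites computed.
#' @return The table with `mirna_rank` and `mrna_rank` filled, rows ordered
#'   by miRNA then `mirna_rank`.
#' @export
rank_bidirectional <- function(scores) {
  need_columns(scores, c("mirna", "gene", "composite"), "score table")
  out <- scores |>
    group_by(.data$mirna) |>
    arrange(desc(.data$composite), .data$gene, .by_group = TRUE) |>
    mutate(mirna_rank = row_number()) |>
    ungroup() |>
    group_by(.data$gene) |>
    arrange(desc(.data$composite), .data$mirna, .by_group = TRUE) |>
    mutate(mrna_rank = row_number()) |>
    ungroup() |>
    arrange(.data$mirna, .data$mirna_rank)
  new_scores(out)
}
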