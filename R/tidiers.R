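#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for mirtev result objects
#'
#' `tidy()` returns the object as a plain tibble (long format for score
#' tables: one row per pair and evidence category); `glance()` returns a
#' one-row summary.
#'
#' @param x An `mt_scores`, `mt_enrichment`, `mt_summary_scores` or
#'   `mt_validation` object.
#' @param ... Unused.
#' @return A tibble.
#' @name mirtev-tidiers
NULL

#' @rdname mirtev-tidiers
#' @method tidy mt_scores
#' @export
tidy.mt_scores <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(c("ectopic", "knockout", "correlation", "prediction"),
                        names_to = "category", values_to = "partial") |>
    select("mirna", "gene", "category", "partial", "composite",
           "availability", "mirna_rank", "mrna_rank")
}

#' @rdname mirtev-tidiers
#' @method glance mt_scores
#' @export
glance.mt_scores <- function(x, ...) {
  tibble(n_pairs = nrow(x), n_mirnas = n_distinct(x$mirna),
         n_genes = n_distinct(x$gene),
         mean_composite = mean(x$composite, na.rm = TRUE),
         median_composite = median(x$composite, na.rm = TRUE),
         max_composite = max(x$composite, na.rm = TRUE))
}

#' @rdname mirtev-tidiers
#' @method tidy mt_enrichment
#' @export
tidy.mt_enrichment <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "summary") <- NULL
  out
}

#' @rdname mirtev-tidiers
#' @method glance mt_enrichment
#' @export
glance.mt_enrichment <- function(x, ...) {
  s <- attr(x, "summary")
  if (!is.null(s)) return(tibble(n_tested = s$n_tested, n_significant = s$n_significant,
                                 alpha = s$alpha))
  tibble(n_tested = nrow(x),
         n_significant = sum(x$fdr < 0.05, na.rm = TRUE),
         alpha = 0.05)
}

#' @rdname mirtev-tidiers
#' @method tidy mt_summary_scores
#' @export
tidy.mt_summary_scores <- function(x, ...) as_tibble(x)

#' @rdname mirtev-tidiers
#' @method glance mt_summary_scores
#' @export
glance.mt_summary_scores <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$kind) |>
    summarise(n_mirnas = n_distinct(.data$mirna), n_entities = n_distinct(.data$entity),
              mean_score = mean(.data$score), .groups = "drop")
}

#' @rdname mirtev-tidiers
#' @method tidy mt_validation
#' @export
tidy.mt_validation <- function(x, ...) x$per_mirna

#' @rdname mirtev-tidiers
#' @method glance mt_validation
#' @export
glance.mt_validation <- function(x, ...) {
  tibble(clean = x$clean, n_unscorable_genes = length(x$unscorable_genes),
         n_orphan_mirnas = length(x$orphan_mirnas))
}

#' Plot methods
#'
#' `autoplot()` gives the standard visual for each result type: composite
#' score distributions per miRNA for score tables, NES (or -log10 FDR for
#' over-representation results) per set for enrichment tables, and
#' diverging summary-score bars per miRNA faceted by entity for clinical
#' summary scores.
#'
#' @param object A mirtev result object.
#' @param top For enrichment results, how many top sets to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @name mirtev-autoplot
NULL

#' @rdname mirtev-autoplot
#' @method autoplot mt_scores
#' @export
autoplot.mt_scores <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$composite, y = .data$mirna)) +
    ggplot2::geom_boxplot(outlier.size = 0.3, fill = "grey85") +
    ggplot2::labs(x = "composite target prediction score", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname mirtev-autoplot
#' @method autoplot mt_enrichment
#' @export
autoplot.mt_enrichment <- function(object, top = 20, ...) {
  d <- as_tibble(object)
  label_col <- if ("mirna" %in% names(d)) "mirna" else "set_name"
  if ("nes" %in% names(d) && any(!is.na(d$nes))) {
    d <- d |> arrange(.data$p) |> head(top)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$nes,
                                    y = stats::reorder(.data[[label_col]], .data$nes),
                                    fill = .data$fdr < 0.05)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "normalized enrichment score", y = NULL, fill = "FDR < 0.05") +
      ggplot2::theme_minimal()
  } else {
    d <- d |> arrange(.data$fdr) |> head(top)
    ggplot2::ggplot(d, ggplot2::aes(x = -log10(pmax(.data$fdr, 1e-300)),
                                    y = stats::reorder(.data[[label_col]], -.data$fdr))) +
      ggplot2::geom_col(fill = "grey40") +
      ggplot2::labs(x = "-log10 FDR", y = NULL) +
      ggplot2::theme_minimal()
  }
}

#' @rdname mirtev-autoplot
#' @method autoplot mt_summary_scores
#' @export
autoplot.mt_summary_scores <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$score, y = .data$mirna,
                               fill = .data$score > 0)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(kind ~ entity) +
    ggplot2::labs(x = "clinical summary score over top targets", y = NULL) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
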