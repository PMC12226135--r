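#' Read and write gene-set collections in GMT format
#'
#' The GMT dialect is one set per line: name, description, then member genes,
#' tab-separated. Descriptions are kept as an attribute on each element.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(setNames(list(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0) {
    abort(sprintf("'%s' line %d: a GMT record needs name, description and >= 1 gene",
                  path, short[1]), class = "mt_format_error")
  }
  sets <- lapply(parts, function(p) unique(trimws(p[-(1:2)])))
  names(sets) <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(names(sets))) {
    abort(sprintf("'%s': duplicate gene-set name '%s'", path,
                  names(sets)[duplicated(names(sets))][1]), class = "mt_format_error")
  }
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a user gene list (one symbol per line)
#'
#' Blank lines and `#` comments are ignored; duplicates are dropped.
#'
#' @param path File path.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- read_lines_clean(path)
  if (length(x) == 0) abort(sprintf("'%s' contains no gene symbols", path),
                            class = "mt_input_error")
  normalize_ids(x, axis = "gene")
}

#' Read a validated-target catalog
#'
#' Expects a TSV with columns `mirna`, `gene`, `pmid` and `assay` (e.g.
#' `luciferase_reporter` or `other`), one experimentally supported
#' miRNA-target record per row; `(mirna, gene, pmid)` must be unique.
#'
#' @param path File path.
#' @return A tibble with the four columns.
#' @export
read_target_catalog <- function(path) {
  x <- read_tsv_checked(path, c("mirna", "gene", "pmid", "assay"))
  x <- as_tibble(x) |> mutate(across(c("mirna", "gene", "pmid", "assay"), as.character))
  dup <- x |> count(.data$mirna, .data$gene, .data$pmid) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate catalog record (%s, %s, PMID %s)",
                  dup$mirna[1], dup$gene[1], dup$pmid[1]), class = "mt_validation_error")
  }
  x
}

# ---- score table I/O --------------------------------------------------------

score_table_cols <- c(
  "mirna", "gene",
  "ectopic", "knockout", "correlation", "prediction",
  "n_ectopic_support", "n_ectopic", "n_knockout_support", "n_knockout",
  "n_correlation_support", "n_correlation", "n_prediction_support", "n_prediction",
  "composite", "n_categories", "availability", "mirna_rank", "mrna_rank"
)

#' Write / read a score table
#'
#' One row per scored (miRNA, gene) pair: the four partial scores (NA when
#' the category has no data for the pair), their supporting/total counts,
#' the composite score, the category-availability mask (a subset of "EKCP"
#' for Ectopic / Knockout / Correlation / Prediction), and both ranks.
#' Doubles are serialized with 17 significant digits so that write -> read
#' is the identity.
#'
#' @param table A score table from [score_targets()].
#' @param path Output TSV path.
#' @param config Optional [mt_config()] recorded in the provenance header.
#' @return `path` invisibly; `read_score_table()` returns the tibble with
#'   class `mt_scores`.
#' @export
write_score_table <- function(table, path, config = NULL) {
  need_columns(table, score_table_cols, "score table")
  out <- table[score_table_cols]
  out <- mutate(out, across(where(is.double),
                            ~ ifelse(is.na(.x), NA_character_, sprintf("%.17g", .x))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  writeLines(readr::format_tsv(out), con, sep = "")
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  x <- read_tsv_checked(path, score_table_cols)
  x <- as_tibble(x) |>
    mutate(
      across(c("mirna", "gene", "availability"), as.character),
      across(c("ectopic", "knockout", "correlation", "prediction", "composite"), as.double),
      across(starts_with("n_"), as.integer),
      across(c("mirna_rank", "mrna_rank"), as.integer)
    )
  new_scores(x[score_table_cols])
}

new_scores <- function(x) {
  class(x) <- unique(c("mt_scores", class(as_tibble(x))))
  x
}

# ---- clinical annotation I/O ------------------------------------------------

annotation_files <- c(de = "differential_expression.tsv", survival = "survival.tsv",
                      dependency = "dependency.tsv", druggable = "druggable.txt")

#' Write / read a clinical annotation set
#'
#' Serializes the differential-expression, survival, dependency and
#' druggability components of an `mt_annotations` object as TSV/plain-text
#' files in `dir`, and reads them back.
#'
#' @param annotations An `mt_annotations` list (see [annotate_clinical()]).
#' @param dir Directory to write into (created if absent).
#' @return `dir` invisibly; `read_annotations()` returns an `mt_annotations`.
#' @export
write_annotations <- function(annotations, dir) {
  stopifnot(inherits(annotations, "mt_annotations"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(annotations$de, file.path(dir, annotation_files[["de"]]))
  readr::write_tsv(annotations$survival, file.path(dir, annotation_files[["survival"]]))
  readr::write_tsv(annotations$dependency, file.path(dir, annotation_files[["dependency"]]))
  writeLines(annotations$druggable, file.path(dir, annotation_files[["druggable"]]))
  invisible(dir)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(dir) {
  de <- read_tsv_checked(file.path(dir, annotation_files[["de"]]),
                         c("entity", "feature", "log2_fold_change", "p", "fdr",
                           "direction", "undetermined"))
  surv <- read_tsv_checked(file.path(dir, annotation_files[["survival"]]),
                           c("entity", "feature", "cutoff", "hazard_ratio",
                             "logrank_p", "direction", "undetermined"))
  dep <- read_tsv_checked(file.path(dir, annotation_files[["dependency"]]),
                          c("entity", "gene", "screen", "fraction_dependent",
                            "dependent", "essential_fraction"))
  druggable <- read_lines_clean(file.path(dir, annotation_files[["druggable"]]))
  new_annotations(de = as_tibble(de), survival = as_tibble(surv),
                  dependency = as_tibble(dep), druggable = druggable)
}

new_annotations <- function(de, survival, dependency, druggable) {
  structure(list(de = de, survival = survival, dependency = dependency,
                 druggable = druggable),
            class = "mt_annotations")
}

#' @export
print.mt_annotations <- function(x, ...) {
  cat("<mt_annotations>\n")
  cat(sprintf("  differential expression: %d feature-entity records (%d entities)\n",
              nrow(x$de), n_distinct(x$de$entity)))
  cat(sprintf("  survival associations:   %d records (%d entities)\n",
              nrow(x$survival), n_distinct(x$survival$entity)))
  cat(sprintf("  dependency calls:        %d records (%d entities)\n",
              nrow(x$dependency), n_distinct(x$dependency$entity)))
  cat(sprintf("  druggable genes:         %d\n", length(x$druggable)))
  invisible(x)
}

#' Write a generic result tibble with a provenance header
#'
#' @param x A tibble.
#' @param path Output TSV path.
#' @param config Optional [mt_config()] recorded in the header.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  writeLines(readr::format_tsv(as_tibble(x)), con, sep = "")
  invisible(path)
}
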