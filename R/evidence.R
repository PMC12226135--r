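#' Evidence bundles
#'
#' An evidence bundle collects, for one miRNA x gene universe, the four
#' evidence categories the composite target score integrates:
#'
#' * `ectopic` — per-dataset linear fold changes (treated / control) of every
#'   measured mRNA after ectopic miRNA expression (mimic or vector); targets
#'   are expected to be repressed.
#' * `knockout` — fold changes after miRNA knockout/knockdown; targets are
#'   expected to be induced.
#' * `correlations` — per-cancer-entity Pearson correlation coefficients
#'   between miRNA and mRNA expression in primary tumors.
#' * `predictions` — positive calls from sequence-based target prediction
#'   algorithms, scored against a fixed algorithm complement.
#'
#' All matrices are held sparse-by-cell in long-format tibbles so that a
#' dataset that did not measure a gene is simply absent (and therefore not
#' evidence against the pair). Identifiers are opaque, case-insensitive
#' strings; each bundle carries canonical spellings in its `genes` and
#' `mirnas` universes.
#'
#' @param ectopic Tibble `(dataset_id, mirna, gene, fold_change)` with
#'   positive linear fold changes; each `dataset_id` references one miRNA.
#' @param knockout Same shape as `ectopic`, for knockout/knockdown datasets.
#' @param correlations Tibble `(entity, mirna, gene, r)` with `|r| <= 1`.
#' @param predictions Tibble `(algorithm, mirna, gene, call)`; only rows with
#'   `call == TRUE` constitute evidence.
#' @param algorithms Character vector: the configured algorithm complement
#'   (the scoring denominator, regardless of how many tools reported a pair).
#' @param genes,mirnas Canonical identifier universes; derived from the data
#'   when omitted.
#' @param ectopic_meta,knockout_meta Optional per-dataset metadata tibbles
#'   `(dataset_id, mirna, intervention, provenance)`.
#'
#' @return A list with class `mt_bundle`.
#' @seealso [load_bundle()], [validate_bundle()], [generate_evidence()]
#' @export
mt_bundle <- function(ectopic = empty_fc_table(),
                      knockout = empty_fc_table(),
                      correlations = empty_cor_table(),
                      predictions = empty_call_table(),
                      algorithms = default_algorithms(),
                      genes = NULL, mirnas = NULL,
                      ectopic_meta = NULL, knockout_meta = NULL) {
  ectopic <- as_fc_table(ectopic, "ectopic")
  knockout <- as_fc_table(knockout, "knockout")
  correlations <- as_cor_table(correlations)
  predictions <- as_call_table(predictions)

  observed_genes <- unique(c(ectopic$gene, knockout$gene, correlations$gene, predictions$gene))
  observed_mirnas <- unique(c(ectopic$mirna, knockout$mirna, correlations$mirna, predictions$mirna))
  genes <- normalize_ids(genes %||% observed_genes, axis = "gene")
  mirnas <- normalize_ids(mirnas %||% observed_mirnas, axis = "miRNA")

  bundle <- structure(
    list(
      ectopic = canon_table(ectopic, genes, mirnas),
      knockout = canon_table(knockout, genes, mirnas),
      correlations = canon_table(correlations, genes, mirnas),
      predictions = canon_table(predictions, genes, mirnas),
      algorithms = as.character(algorithms),
      genes = genes, mirnas = mirnas,
      ectopic_meta = ectopic_meta, knockout_meta = knockout_meta
    ),
    class = "mt_bundle"
  )
  check_bundle_invariants(bundle)
  bundle
}

empty_fc_table <- function() {
  tibble(dataset_id = character(), mirna = character(),
         gene = character(), fold_change = double())
}
empty_cor_table <- function() {
  tibble(entity = character(), mirna = character(), gene = character(), r = double())
}
empty_call_table <- function() {
  tibble(algorithm = character(), mirna = character(), gene = character(), call = logical())
}

as_fc_table <- function(x, what) {
  x <- as_tibble(x)
  need_columns(x, c("dataset_id", "mirna", "gene", "fold_change"), paste0(what, " table"))
  x$fold_change <- as.double(x$fold_change)
  bad <- which(!is.finite(x$fold_change) | x$fold_change <= 0)
  if (length(bad) > 0) {
    i <- bad[1]
    abort(sprintf(
      "%s fold changes must be positive reals: dataset '%s', gene '%s' has value %s (%d offending cell%s)",
      what, x$dataset_id[i], x$gene[i], format(x$fold_change[i]),
      length(bad), if (length(bad) > 1) "s" else ""
    ), class = "mt_validation_error")
  }
  multi <- x |> distinct(.data$dataset_id, .data$mirna) |> count(.data$dataset_id) |> filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort(sprintf("%s dataset '%s' references more than one miRNA", what, multi$dataset_id[1]),
          class = "mt_validation_error")
  }
  dup <- x |> count(.data$dataset_id, .data$gene) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate %s measurement for dataset '%s', gene '%s'",
                  what, dup$dataset_id[1], dup$gene[1]), class = "mt_validation_error")
  }
  x[c("dataset_id", "mirna", "gene", "fold_change")]
}

as_cor_table <- function(x) {
  x <- as_tibble(x)
  need_columns(x, c("entity", "mirna", "gene", "r"), "correlation table")
  x$r <- as.double(x$r)
  bad <- which(!is.na(x$r) & abs(x$r) > 1)
  if (length(bad) > 0) {
    i <- bad[1]
    abort(sprintf("Pearson coefficients must satisfy |r| <= 1: entity '%s', pair (%s, %s) has r = %s",
                  x$entity[i], x$mirna[i], x$gene[i], format(x$r[i])),
          class = "mt_validation_error")
  }
  dup <- x |> count(.data$entity, .data$mirna, .data$gene) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate correlation cell for entity '%s', pair (%s, %s)",
                  dup$entity[1], dup$mirna[1], dup$gene[1]), class = "mt_validation_error")
  }
  x <- x[!is.na(x$r), ]
  x[c("entity", "mirna", "gene", "r")]
}

as_call_table <- function(x) {
  x <- as_tibble(x)
  if (!"call" %in% names(x)) x$call <- TRUE
  need_columns(x, c("algorithm", "mirna", "gene", "call"), "prediction table")
  x$call <- as.logical(x$call)
  dup <- x |> count(.data$algorithm, .data$mirna, .data$gene) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate prediction call for algorithm '%s', pair (%s, %s)",
                  dup$algorithm[1], dup$mirna[1], dup$gene[1]), class = "mt_validation_error")
  }
  x[c("algorithm", "mirna", "gene", "call")]
}

need_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what, paste(missing, collapse = ", ")),
          class = "mt_format_error")
  }
  invisible(x)
}

#' Normalize identifiers
#'
#' Trims whitespace and unifies case-insensitive duplicates onto the first
#' spelling seen, so identifier matching is case-insensitive while outputs
#' keep a stable canonical form. Idempotent.
#'
#' @param ids Character vector of identifiers.
#' @param axis Label used in error messages ("gene", "miRNA").
#' @return Character vector of unique canonical identifiers.
#' @export
normalize_ids <- function(ids, axis = "identifier") {
  ids <- trimws(as.character(ids))
  if (any(!nzchar(ids))) {
    abort(sprintf("empty %s identifier", axis), class = "mt_validation_error")
  }
  ids[!duplicated(tolower(ids))]
}

# map every identifier column of a long table onto the canonical universes
canon_table <- function(x, genes, mirnas) {
  if (nrow(x) == 0) return(x)
  if ("gene" %in% names(x)) x$gene <- canon_match(x$gene, genes, "gene")
  if ("mirna" %in% names(x)) x$mirna <- canon_match(x$mirna, mirnas, "miRNA")
  x
}

canon_match <- function(ids, universe, axis) {
  ids <- trimws(as.character(ids))
  m <- match(tolower(ids), tolower(universe))
  if (anyNA(m)) {
    missing <- unique(ids[is.na(m)])
    abort(sprintf("%s identifier(s) not in the declared universe: %s",
                  axis, paste(head(missing, 5), collapse = ", ")),
          class = "mt_validation_error")
  }
  universe[m]
}

check_bundle_invariants <- function(bundle) {
  stopifnot(is.character(bundle$algorithms))
  if (anyDuplicated(tolower(bundle$genes)) || anyDuplicated(tolower(bundle$mirnas))) {
    abort("duplicate identifiers within a universe axis", class = "mt_validation_error")
  }
  invisible(bundle)
}

#' @export
print.mt_bundle <- function(x, ...) {
  cat("<mt_bundle>\n")
  cat(sprintf("  universes:    %d miRNAs x %d genes\n", length(x$mirnas), length(x$genes)))
  cat(sprintf("  ectopic:      %d datasets, %d cells\n",
              n_distinct(x$ectopic$dataset_id), nrow(x$ectopic)))
  cat(sprintf("  knockout:     %d datasets, %d cells\n",
              n_distinct(x$knockout$dataset_id), nrow(x$knockout)))
  cat(sprintf("  correlations: %d entities, %d cells\n",
              n_distinct(x$correlations$entity), nrow(x$correlations)))
  cat(sprintf("  predictions:  %d/%d algorithms reporting, %d positive calls\n",
              n_distinct(x$predictions$algorithm), length(x$algorithms),
              sum(x$predictions$call)))
  invisible(x)
}

# ---- bundle directory I/O ---------------------------------------------------

bundle_files <- c(
  ectopic = "ectopic.tsv", knockout = "knockout.tsv",
  correlations = "correlations.tsv", predictions = "predictions.tsv",
  algorithms = "algorithms.txt", genes = "genes.txt", mirnas = "mirnas.txt",
  ectopic_meta = "ectopic_datasets.tsv", knockout_meta = "knockout_datasets.tsv"
)

#' Load an evidence bundle from a directory of long-format TSV files
#'
#' Expects `ectopic.tsv` and `knockout.tsv` (`dataset_id  mirna  gene
#' fold_change`), `correlations.tsv` (`entity  mirna  gene  r`),
#' `predictions.tsv` (`algorithm  mirna  gene  call`), `algorithms.txt`
#' (one tool name per line, the scoring complement) and optionally
#' `genes.txt` / `mirnas.txt` declaring the identifier universes and
#' `*_datasets.tsv` metadata. Missing evidence files yield empty categories
#' with a warning; malformed files raise format errors naming the file.
#'
#' @param dir Directory containing the bundle files.
#' @param quiet Suppress the per-category load report.
#' @return A validated [mt_bundle()].
#' @export
load_bundle <- function(dir, quiet = FALSE) {
  if (!dir.exists(dir)) {
    abort(sprintf("bundle directory '%s' does not exist", dir), class = "mt_io_error")
  }
  path <- function(key) file.path(dir, bundle_files[[key]])
  read_part <- function(key, empty, cols) {
    p <- path(key)
    if (!file.exists(p)) {
      warn(sprintf("bundle has no %s table ('%s' absent); category left empty",
                   key, bundle_files[[key]]))
      return(empty)
    }
    x <- read_tsv_checked(p, cols)
    x
  }
  ectopic <- read_part("ectopic", empty_fc_table(), c("dataset_id", "mirna", "gene", "fold_change"))
  knockout <- read_part("knockout", empty_fc_table(), c("dataset_id", "mirna", "gene", "fold_change"))
  correlations <- read_part("correlations", empty_cor_table(), c("entity", "mirna", "gene", "r"))
  predictions <- read_part("predictions", empty_call_table(), c("algorithm", "mirna", "gene", "call"))

  algorithms <- if (file.exists(path("algorithms"))) {
    read_lines_clean(path("algorithms"))
  } else {
    unique(predictions$algorithm)
  }
  genes <- if (file.exists(path("genes"))) read_lines_clean(path("genes")) else NULL
  mirnas <- if (file.exists(path("mirnas"))) read_lines_clean(path("mirnas")) else NULL
  meta <- function(key) {
    p <- path(key)
    if (file.exists(p)) read_tsv_checked(p, c("dataset_id", "mirna", "intervention")) else NULL
  }

  bundle <- mt_bundle(
    ectopic = ectopic, knockout = knockout, correlations = correlations,
    predictions = predictions, algorithms = algorithms,
    genes = genes, mirnas = mirnas,
    ectopic_meta = meta("ectopic_meta"), knockout_meta = meta("knockout_meta")
  )
  if (!quiet) {
    inform(sprintf(
      "loaded bundle: %d ectopic datasets, %d knockout datasets, %d correlation entities, %d algorithms, %d miRNAs, %d genes",
      n_distinct(bundle$ectopic$dataset_id), n_distinct(bundle$knockout$dataset_id),
      n_distinct(bundle$correlations$entity), length(bundle$algorithms),
      length(bundle$mirnas), length(bundle$genes)
    ))
  }
  bundle
}

#' Write an evidence bundle to a directory
#'
#' Emits the exact TSV dialect [load_bundle()] reads, plus the universe and
#' algorithm sidecars, so write -> load is the identity.
#'
#' @param bundle An [mt_bundle()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "mt_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(key) file.path(dir, bundle_files[[key]])
  readr::write_tsv(bundle$ectopic, p("ectopic"))
  readr::write_tsv(bundle$knockout, p("knockout"))
  readr::write_tsv(bundle$correlations, p("correlations"))
  readr::write_tsv(bundle$predictions, p("predictions"))
  writeLines(bundle$algorithms, p("algorithms"))
  writeLines(bundle$genes, p("genes"))
  writeLines(bundle$mirnas, p("mirnas"))
  if (!is.null(bundle$ectopic_meta)) readr::write_tsv(bundle$ectopic_meta, p("ectopic_meta"))
  if (!is.null(bundle$knockout_meta)) readr::write_tsv(bundle$knockout_meta, p("knockout_meta"))
  invisible(dir)
}

read_tsv_checked <- function(path, cols) {
  x <- tryCatch(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("failed to parse '%s': %s", path, conditionMessage(e)),
                              class = "mt_format_error")
  )
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf("'%s' header (line 1) lacks required column(s): %s",
                  path, paste(missing, collapse = ", ")), class = "mt_format_error")
  }
  x
}

read_lines_clean <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

# ---- validation report ------------------------------------------------------

#' Summarize coverage and consistency of an evidence bundle
#'
#' Report-only: never fails. Lists per-miRNA dataset counts for each
#' category (and the mean studies per miRNA, the kind of figure quoted when
#' describing such compendia), universe members with no data in any category
#' (unscorable), and missing-cell fractions relative to the full
#' miRNA-x-gene grid.
#'
#' @param bundle An [mt_bundle()].
#' @return A list with class `mt_validation`: `per_mirna` (tibble of dataset
#'   counts per category), `category_summary`, `unscorable_genes`,
#'   `orphan_mirnas`, `clean` (logical).
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "mt_bundle"))
  ect <- bundle$ectopic |> distinct(.data$dataset_id, .data$mirna) |> count(.data$mirna, name = "n_ectopic")
  ko <- bundle$knockout |> distinct(.data$dataset_id, .data$mirna) |> count(.data$mirna, name = "n_knockout")
  cor_ <- bundle$correlations |> distinct(.data$entity, .data$mirna) |> count(.data$mirna, name = "n_entities")
  pred <- bundle$predictions |> filter(.data$call) |> distinct(.data$algorithm, .data$mirna) |>
    count(.data$mirna, name = "n_algorithms")
  per_mirna <- tibble(mirna = bundle$mirnas) |>
    left_join(ect, by = "mirna") |> left_join(ko, by = "mirna") |>
    left_join(cor_, by = "mirna") |> left_join(pred, by = "mirna") |>
    mutate(across(starts_with("n_"), ~ tidyr::replace_na(.x, 0L)))

  summarize_cat <- function(col, n_sets) {
    covered <- per_mirna[[col]] > 0
    tibble(
      category = sub("^n_", "", col),
      n_datasets = n_sets,
      n_mirnas_covered = sum(covered),
      mean_per_covered_mirna = if (any(covered)) mean(per_mirna[[col]][covered]) else NA_real_
    )
  }
  category_summary <- bind_rows(
    summarize_cat("n_ectopic", n_distinct(bundle$ectopic$dataset_id)),
    summarize_cat("n_knockout", n_distinct(bundle$knockout$dataset_id)),
    summarize_cat("n_entities", n_distinct(bundle$correlations$entity)),
    summarize_cat("n_algorithms", n_distinct(bundle$predictions$algorithm[bundle$predictions$call]))
  )

  genes_seen <- unique(c(bundle$ectopic$gene, bundle$knockout$gene,
                         bundle$correlations$gene,
                         bundle$predictions$gene[bundle$predictions$call]))
  unscorable_genes <- setdiff(bundle$genes, genes_seen)
  orphan_mirnas <- per_mirna |>
    filter(.data$n_ectopic + .data$n_knockout + .data$n_entities + .data$n_algorithms == 0) |>
    pull("mirna")

  grid <- length(bundle$mirnas) * length(bundle$genes)
  missing_fraction <- tibble(
    category = c("ectopic", "knockout", "correlations"),
    missing_cell_fraction = c(
      missing_frac(bundle$ectopic |> distinct(.data$mirna, .data$gene), grid),
      missing_frac(bundle$knockout |> distinct(.data$mirna, .data$gene), grid),
      missing_frac(bundle$correlations |> distinct(.data$mirna, .data$gene), grid)
    )
  )

  structure(
    list(per_mirna = per_mirna, category_summary = category_summary,
         unscorable_genes = unscorable_genes, orphan_mirnas = orphan_mirnas,
         missing_fraction = missing_fraction,
         clean = length(unscorable_genes) == 0 && length(orphan_mirnas) == 0),
    class = "mt_validation"
  )
}

missing_frac <- function(pairs, grid) {
  if (grid == 0) return(NA_real_)
  1 - nrow(pairs) / grid
}

#' @export
print.mt_validation <- function(x, ...) {
  cat("<mt_validation>", if (x$clean) "clean" else "with findings", "\n")
  print(x$category_summary)
  if (length(x$unscorable_genes) > 0) {
    cat(sprintf("unscorable genes (%d): %s\n", length(x$unscorable_genes),
                paste(head(x$unscorable_genes, 5), collapse = ", ")))
  }
  if (length(x$orphan_mirnas) > 0) {
    cat(sprintf("miRNAs with no data (%d): %s\n", length(x$orphan_mirnas),
                paste(head(x$orphan_mirnas, 5), collapse = ", ")))
  }
  invisible(x)
}
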