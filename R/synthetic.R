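#' Default effect parameters for the synthetic generator
#'
#' The generator emulates, at desk scale, the structure of the compendia
#' the scoring method integrates: per-dataset linear fold changes with
#' log-normal noise, per-entity Pearson correlations jittered on the
#' Fisher-z scale, and binomial prediction support. Planted miRNA-target
#' pairs receive a true repression fold of 0.5 in ectopic datasets, a true
#' induction fold of 2.0 in knockout datasets, a true correlation of -0.4
#' and prediction support of ~8/10 tools; decoys are centred on no effect.
#'
#' @return Named list of effect parameters.
#' @export
default_effects <- function() {
  list(
    repression_fc = 0.5,    # true ectopic fold change of a planted target
    induction_fc = 2.0,     # true knockout fold change
    correlation = -0.4,     # true tumor-expression correlation
    prediction_support = 8, # expected positive calls out of the complement
    fc_sdlog = 0.15,        # log-normal noise around planted fold changes
    null_fc_sdlog = 0.25,   # log-normal noise of decoy fold changes (around 1)
    cor_sd = 0.15,          # Fisher-z jitter of correlations
    decoy_call_rate = 0.05, # per-algorithm positive-call rate for decoys
    measured_fraction = 0.9,# fraction of cells actually measured per dataset
    de_lfc = 1.5,           # planted tumor/normal log2 shift
    risk_coupling = 0.8,    # expression loading on the latent survival risk
    survival_beta = log(2.5), # log hazard ratio per risk-unit
    dependency_fraction = 0.3, # planted fraction of dependent cell lines
    druggable_rate = 0.2    # fraction of planted target genes marked druggable
  )
}

#' Generate a synthetic evidence bundle with planted ground truth
#'
#' Seeded generator of a complete four-category evidence bundle. A fraction
#' of genes per miRNA is planted as true targets; planted pairs draw
#' repressed ectopic fold changes, induced knockout fold changes, negative
#' correlations and high prediction support, while decoy pairs draw null
#' noise. Each miRNA is assigned a clinical class — `suppressor` (miRNA
#' down in tumors, good survival; its targets up in tumors, poor survival),
#' `oncomir` (mirror) or `neutral` — recorded in the ground-truth ledger
#' and consumed by [generate_clinical()].
#'
#' The default sizes mimic the proportions of the real compendia at small
#' scale: ~4 ectopic and ~3 knockout studies per miRNA and a two-digit
#' number of correlation entities.
#'
#' @param n_mirnas,n_genes Universe sizes.
#' @param n_ectopic_per_mirna,n_ko_per_mirna Datasets per miRNA.
#' @param n_entities Correlation panels (cancer entities).
#' @param planted_fraction Fraction of genes planted as true targets of
#'   each miRNA, in (0, 1).
#' @param effects Effect parameters, see [default_effects()].
#' @param seed Integer seed; identical seeds give identical output.
#' @param algorithms Prediction-algorithm complement.
#' @return A list `(bundle, ledger)`: the [mt_bundle()] and an `mt_ledger`
#'   list with `planted` (tibble of planted pairs and their true effects),
#'   `mirna_profile`, `gene_profile`, `catalog` (a synthetic
#'   validated-target catalog drawn from planted pairs), `params`, `seed`.
#' @export
generate_evidence <- function(n_mirnas = 20, n_genes = 2000,
                              n_ectopic_per_mirna = 4, n_ko_per_mirna = 3,
                              n_entities = 10, planted_fraction = 0.05,
                              effects = default_effects(), seed = 1L,
                              algorithms = default_algorithms()) {
  if (n_mirnas < 1 || n_genes < 2 || n_entities < 1 ||
      n_ectopic_per_mirna < 0 || n_ko_per_mirna < 0) {
    abort("generator sizes must be >= 1 (datasets per miRNA >= 0)", class = "mt_config_error")
  }
  if (!(planted_fraction > 0 && planted_fraction < 1)) {
    abort("`planted_fraction` must lie in (0, 1)", class = "mt_config_error")
  }
  effects <- modifyList(default_effects(), effects)
  set.seed(seed)

  mirnas <- sprintf("miR-%03d", seq_len(n_mirnas))
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  entities <- sprintf("ENT%02d", seq_len(n_entities))
  n_algos <- length(algorithms)

  classes <- rep(c("suppressor", "oncomir"), length.out = n_mirnas)
  k_planted <- max(1L, round(planted_fraction * n_genes))
  planted <- purrr::map_dfr(seq_len(n_mirnas), function(i) {
    tibble(mirna = mirnas[i],
           gene = sort(sample(genes, k_planted)),
           mirna_class = classes[i])
  })
  planted <- planted |>
    mutate(
      repression_fc = effects$repression_fc,
      induction_fc = effects$induction_fc,
      correlation = effects$correlation,
      prediction_support = pmin(n_algos, pmax(0L, rbinom(n(), n_algos,
                                                         effects$prediction_support / n_algos)))
    )

  is_planted_key <- paste(planted$mirna, planted$gene)

  fc_category <- function(n_per_mirna, true_fc, prefix) {
    if (n_per_mirna == 0) return(empty_fc_table())
    purrr::map_dfr(seq_len(n_mirnas), function(i) {
      purrr::map_dfr(seq_len(n_per_mirna), function(d) {
        measured <- sample(genes, round(effects$measured_fraction * n_genes))
        pl <- measured %in% planted$gene[planted$mirna == mirnas[i]]
        fc <- numeric(length(measured))
        fc[pl] <- rlnorm(sum(pl), meanlog = log(true_fc), sdlog = effects$fc_sdlog)
        fc[!pl] <- rlnorm(sum(!pl), meanlog = 0, sdlog = effects$null_fc_sdlog)
        tibble(dataset_id = sprintf("%s_%s_d%02d", prefix, mirnas[i], d),
               mirna = mirnas[i], gene = measured, fold_change = fc)
      })
    })
  }
  ectopic <- fc_category(n_ectopic_per_mirna, effects$repression_fc, "ect")
  knockout <- fc_category(n_ko_per_mirna, effects$induction_fc, "ko")

  correlations <- purrr::map_dfr(entities, function(ent) {
    purrr::map_dfr(seq_len(n_mirnas), function(i) {
      measured <- sample(genes, round(effects$measured_fraction * n_genes))
      pl <- measured %in% planted$gene[planted$mirna == mirnas[i]]
      z0 <- ifelse(pl, atanh(effects$correlation), 0)
      r <- tanh(z0 + rnorm(length(measured), 0, effects$cor_sd))
      tibble(entity = ent, mirna = mirnas[i], gene = measured, r = r)
    })
  })

  # positive calls only; planted pairs draw their planted support count,
  # decoys are per-algorithm Bernoulli noise
  planted_calls <- purrr::map_dfr(seq_len(nrow(planted)), function(j) {
    k <- planted$prediction_support[j]
    if (k == 0) return(empty_call_table())
    tibble(algorithm = sample(algorithms, k), mirna = planted$mirna[j],
           gene = planted$gene[j], call = TRUE)
  })
  decoy_calls <- purrr::map_dfr(seq_len(n_mirnas), function(i) {
    decoys <- setdiff(genes, planted$gene[planted$mirna == mirnas[i]])
    k <- rbinom(length(decoys), n_algos, effects$decoy_call_rate)
    idx <- which(k > 0)
    if (length(idx) == 0) return(empty_call_table())
    purrr::map_dfr(idx, function(j) {
      tibble(algorithm = sample(algorithms, k[j]), mirna = mirnas[i],
             gene = decoys[j], call = TRUE)
    })
  })

  meta <- function(tbl, intervention) {
    if (nrow(tbl) == 0) return(NULL)
    tbl |> distinct(.data$dataset_id, .data$mirna) |>
      mutate(intervention = intervention, provenance = "synthetic")
  }
  bundle <- mt_bundle(
    ectopic = ectopic, knockout = knockout, correlations = correlations,
    predictions = bind_rows(planted_calls, decoy_calls),
    algorithms = algorithms, genes = genes, mirnas = mirnas,
    ectopic_meta = meta(ectopic, "ectopic"),
    knockout_meta = meta(knockout, "knockout_knockdown")
  )

  mirna_profile <- tibble(mirna = mirnas, class = classes) |>
    mutate(
      de_direction = case_when(.data$class == "suppressor" ~ "down_in_tumor",
                               .data$class == "oncomir" ~ "up_in_tumor",
                               TRUE ~ "ns"),
      survival_direction = case_when(.data$class == "suppressor" ~ "good_with_high",
                                     .data$class == "oncomir" ~ "poor_with_high",
                                     TRUE ~ "ns"),
      lfc = ifelse(.data$de_direction == "down_in_tumor", -effects$de_lfc,
                   ifelse(.data$de_direction == "up_in_tumor", effects$de_lfc, 0))
    )

  # a gene targeted by any suppressor miRNA behaves oncogenically; oncomir
  # targets behave suppressively; conflicts resolve by majority vote
  gene_vote <- planted |>
    mutate(vote = ifelse(.data$mirna_class == "suppressor", 1L, -1L)) |>
    group_by(.data$gene) |>
    summarise(vote = sum(.data$vote), .groups = "drop")
  gene_profile <- tibble(gene = genes) |>
    left_join(gene_vote, by = "gene") |>
    mutate(
      vote = tidyr::replace_na(.data$vote, 0L),
      de_direction = case_when(.data$vote > 0 ~ "up_in_tumor",
                               .data$vote < 0 ~ "down_in_tumor",
                               TRUE ~ "ns"),
      survival_direction = case_when(.data$vote > 0 ~ "poor_with_high",
                                     .data$vote < 0 ~ "good_with_high",
                                     TRUE ~ "ns"),
      lfc = sign(.data$vote) * effects$de_lfc,
      dependency_fraction = ifelse(.data$vote > 0, effects$dependency_fraction, 0),
      druggable = .data$vote > 0 & runif(n()) < effects$druggable_rate
    ) |>
    select(-"vote")

  catalog <- planted |>
    group_by(.data$mirna) |>
    slice_sample(prop = 0.5) |>
    ungroup() |>
    transmute(.data$mirna, .data$gene,
              pmid = sprintf("9%07d", seq_len(n())),
              assay = "luciferase_reporter")

  ledger <- structure(
    list(planted = planted, mirna_profile = mirna_profile,
         gene_profile = gene_profile, catalog = catalog,
         entities = entities, seed = seed,
         params = list(n_mirnas = n_mirnas, n_genes = n_genes,
                       n_ectopic_per_mirna = n_ectopic_per_mirna,
                       n_ko_per_mirna = n_ko_per_mirna,
                       n_entities = n_entities,
                       planted_fraction = planted_fraction,
                       effects = effects, algorithms = algorithms)),
    class = "mt_ledger"
  )
  list(bundle = bundle, ledger = ledger)
}

#' Generate synthetic clinical tables matching a ground-truth ledger
#'
#' Produces, per entity: a log2 expression matrix over all genes and
#' miRNAs with tumor and normal samples (tumor samples shifted by each
#' feature's planted log2 fold change); overall survival for tumor samples
#' driven by a latent risk variable that planted poor-survival features
#' load on positively (and good-survival features negatively), with
#' exponential event times and uniform censoring; gene-effect values for
#' CRISPR and RNAi screens with the planted dependent fractions; and the
#' druggable gene list.
#'
#' @param ledger An `mt_ledger` from [generate_evidence()].
#' @param n_tumor,n_normal Samples per entity.
#' @param n_lines Cell lines per entity and screen.
#' @param seed Integer seed (independent of the evidence seed).
#' @return A list with class `mt_clinical`: `expr` (named list of feature x
#'   sample matrices), `samples` (tibble `sample, entity, group, time,
#'   event`), `depmap` (long gene-effect tibble), `druggable`.
#' @export
generate_clinical <- function(ledger, n_tumor = 30, n_normal = 30,
                              n_lines = 25, seed = ledger$seed + 1000L) {
  stopifnot(inherits(ledger, "mt_ledger"))
  set.seed(seed)
  eff <- ledger$params$effects
  features <- c(ledger$gene_profile$gene, ledger$mirna_profile$mirna)
  lfc <- c(ledger$gene_profile$lfc, ledger$mirna_profile$lfc)
  surv_dir <- c(ledger$gene_profile$survival_direction,
                ledger$mirna_profile$survival_direction)
  load_ <- ifelse(surv_dir == "poor_with_high", eff$risk_coupling,
                  ifelse(surv_dir == "good_with_high", -eff$risk_coupling, 0))
  base <- rnorm(length(features), mean = 6, sd = 1.5)

  expr <- list(); samples <- list(); depmap <- list()
  for (ent in ledger$entities) {
    n <- n_tumor + n_normal
    group <- rep(c("tumor", "normal"), c(n_tumor, n_normal))
    risk <- c(rnorm(n_tumor), rep(NA_real_, n_normal))
    m <- matrix(rnorm(length(features) * n, sd = 1), nrow = length(features))
    m <- m + base
    m[, group == "tumor"] <- m[, group == "tumor"] + lfc
    m[, group == "tumor"] <- m[, group == "tumor"] +
      outer(load_, risk[group == "tumor"])
    rownames(m) <- features
    colnames(m) <- sprintf("%s_s%03d", ent, seq_len(n))

    t_event <- rexp(n_tumor, rate = 0.002 * exp(eff$survival_beta * risk[group == "tumor"]))
    t_cens <- runif(n_tumor, 100, 2000)
    time <- rep(NA_real_, n); event <- rep(NA_integer_, n)
    time[group == "tumor"] <- pmin(t_event, t_cens)
    event[group == "tumor"] <- as.integer(t_event <= t_cens)

    expr[[ent]] <- m
    samples[[ent]] <- tibble(sample = colnames(m), entity = ent,
                             group = group, time = time, event = event)

    dep_frac <- ledger$gene_profile$dependency_fraction
    dep_gene <- ledger$gene_profile$gene
    for (screen in c("crispr", "rnai")) {
      dep <- matrix(rnorm(length(dep_gene) * n_lines, mean = 0, sd = 0.15),
                    nrow = length(dep_gene))
      hit <- matrix(runif(length(dep_gene) * n_lines), nrow = length(dep_gene)) < dep_frac
      dep[hit] <- rnorm(sum(hit), mean = -0.8, sd = 0.1)
      depmap[[paste(ent, screen)]] <- tibble(
        entity = ent,
        cell_line = rep(sprintf("%s_%s_cl%02d", ent, screen, seq_len(n_lines)),
                        each = length(dep_gene)),
        gene = rep(dep_gene, times = n_lines),
        effect = as.vector(dep),
        screen = screen
      )
    }
  }

  structure(list(expr = expr, samples = bind_rows(samples),
                 depmap = bind_rows(depmap),
                 druggable = ledger$gene_profile$gene[ledger$gene_profile$druggable]),
            class = "mt_clinical")
}

#' Write / read synthetic clinical tables
#'
#' One wide expression TSV per entity (`expr_<entity>.tsv`, feature column
#' plus one column per sample), a `samples.tsv` sidecar, a long
#' `depmap.tsv` and `druggable.txt`.
#'
#' @param clinical An `mt_clinical` list.
#' @param dir Directory.
#' @return `dir` invisibly; `read_clinical()` returns an `mt_clinical`.
#' @export
write_clinical <- function(clinical, dir) {
  stopifnot(inherits(clinical, "mt_clinical"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ent in names(clinical$expr)) {
    m <- clinical$expr[[ent]]
    readr::write_tsv(bind_cols(tibble(feature = rownames(m)), as_tibble(m)),
                     file.path(dir, sprintf("expr_%s.tsv", ent)))
  }
  readr::write_tsv(clinical$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(clinical$depmap, file.path(dir, "depmap.tsv"))
  writeLines(clinical$druggable, file.path(dir, "druggable.txt"))
  invisible(dir)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(dir) {
  samples <- read_tsv_checked(file.path(dir, "samples.tsv"),
                              c("sample", "entity", "group", "time", "event"))
  files <- list.files(dir, pattern = "^expr_.*\\.tsv$", full.names = TRUE)
  expr <- lapply(files, function(f) {
    x <- readr::read_tsv(f, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(x[-1])
    rownames(m) <- x$feature
    m
  })
  names(expr) <- sub("^expr_(.*)\\.tsv$", "\\1", basename(files))
  depmap <- read_tsv_checked(file.path(dir, "depmap.tsv"),
                             c("entity", "cell_line", "gene", "effect", "screen"))
  drug_path <- file.path(dir, "druggable.txt")
  druggable <- if (file.exists(drug_path)) read_lines_clean(drug_path) else character()
  structure(list(expr = expr, samples = as_tibble(samples),
                 depmap = as_tibble(depmap), druggable = druggable),
            class = "mt_clinical")
}

#' Simulate a survival cohort with a planted expression cutoff
#'
#' Small helper for parameter-recovery checks of
#' [survival_association()]: samples above the planted expression quantile
#' have their event hazard multiplied by `hr`.
#'
#' @param n Cohort size.
#' @param hr Planted hazard ratio (high vs low expression).
#' @param cutoff_quantile Planted split quantile.
#' @param base_rate Baseline exponential event rate.
#' @param censor_range Uniform censoring window.
#' @param seed Integer seed.
#' @return Tibble `(expr, time, event, high)` plus attribute `cutoff`
#'   (the planted expression threshold).
#' @export
simulate_survival_cohort <- function(n = 200, hr = 3, cutoff_quantile = 0.5,
                                     base_rate = 0.002,
                                     censor_range = c(200, 3000), seed = 1L) {
  set.seed(seed)
  expr <- rnorm(n, mean = 5, sd = 1)
  cutoff <- quantile(expr, cutoff_quantile, names = FALSE)
  high <- expr > cutoff
  t_event <- rexp(n, rate = base_rate * ifelse(high, hr, 1))
  t_cens <- runif(n, censor_range[1], censor_range[2])
  out <- tibble(expr = expr, time = pmin(t_event, t_cens),
                event = as.integer(t_event <= t_cens), high = high)
  attr(out, "cutoff") <- cutoff
  out
}

#' @export
print.mt_ledger <- function(x, ...) {
  cat("<mt_ledger>\n")
  cat(sprintf("  %d planted pairs over %d miRNAs x %d genes, seed %d\n",
              nrow(x$planted), x$params$n_mirnas, x$params$n_genes, x$seed))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$mirna_profile$class)),
                            table(x$mirna_profile$class)), collapse = ", ")))
  invisible(x)
}
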