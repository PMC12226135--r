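#' Analysis configuration
#'
#' Collects every tunable constant of the pipeline in one validated list.
#' Defaults are the method's published operating points: an mRNA counts as
#' repressed when its linear fold change after ectopic miRNA expression is
#' below `fc_down` (0.8, i.e. >1.25-fold repression), induced after miRNA
#' knockout/knockdown when above `fc_up` (1.25), anti-correlated when the
#' Pearson coefficient is below `r_cut` (-0.1). The prediction-algorithm
#' partial is scored against the fixed complement in `algorithms` (ten tools
#' by default), not against however many tools happened to report a pair.
#'
#' @param fc_down Repression cutoff for ectopic-expression datasets, linear
#'   fold change in (0, 1). Strict: a fold change equal to the cutoff does
#'   not count as repression.
#' @param fc_up Induction cutoff for knockout/knockdown datasets, linear fold
#'   change greater than 1. Strict.
#' @param r_cut Anti-correlation cutoff for tumor expression panels, in
#'   (-1, 0). Strict.
#' @param alpha Significance level applied to BH-adjusted p-values when
#'   labelling differential-expression and survival directions.
#' @param dep_effect Gene-effect threshold below which a cell line counts as
#'   dependent (strict `<`).
#' @param dep_frac Minimum fraction of cell lines (inclusive `>=`) below
#'   `dep_effect` for a gene to be flagged dependent in an entity.
#' @param top_k Size of the per-miRNA top target set used by summary scores
#'   and list enrichment.
#' @param n_perm Number of gene-label permutations for preranked GSEA.
#' @param seed Default random seed for seeded operations.
#' @param algorithms Character vector naming the prediction-algorithm
#'   complement; its length is the denominator of the prediction partial.
#' @param use_adjusted_p Logical; direction labels use BH-adjusted p-values
#'   when `TRUE` (default), raw p-values otherwise.
#'
#' @return A named list with class `mt_config`.
#' @examples
#' cfg <- mt_config()
#' cfg$fc_down
#' @export
mt_config <- function(fc_down = 0.8,
                      fc_up = 1.25,
                      r_cut = -0.1,
                      alpha = 0.05,
                      dep_effect = -0.5,
                      dep_frac = 0.10,
                      top_k = 1000,
                      n_perm = 1000,
                      seed = 1L,
                      algorithms = default_algorithms(),
                      use_adjusted_p = TRUE) {
  cfg <- list(
    fc_down = fc_down, fc_up = fc_up, r_cut = r_cut, alpha = alpha,
    dep_effect = dep_effect, dep_frac = dep_frac, top_k = as.integer(top_k),
    n_perm = as.integer(n_perm), seed = as.integer(seed),
    algorithms = as.character(algorithms),
    use_adjusted_p = isTRUE(use_adjusted_p)
  )
  validate_config(cfg)
  structure(cfg, class = "mt_config")
}

#' @rdname mt_config
#' @export
default_algorithms <- function() sprintf("tool%02d", 1:10)

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$fc_down), is.numeric(cfg$fc_up), is.numeric(cfg$r_cut))
  if (!(cfg$fc_down > 0 && cfg$fc_down < 1)) {
    abort(sprintf("`fc_down` must lie in (0, 1), got %s: values >= 1 would count inductions as repression", cfg$fc_down),
          class = "mt_config_error")
  }
  if (!(cfg$fc_up > 1)) {
    abort(sprintf("`fc_up` must exceed 1, got %s", cfg$fc_up), class = "mt_config_error")
  }
  if (!(cfg$r_cut > -1 && cfg$r_cut < 0)) {
    abort(sprintf("`r_cut` must lie in (-1, 0), got %s", cfg$r_cut), class = "mt_config_error")
  }
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) {
    abort("`alpha` must lie in (0, 1)", class = "mt_config_error")
  }
  if (!(cfg$dep_frac >= 0 && cfg$dep_frac <= 1)) {
    abort("`dep_frac` must lie in [0, 1]", class = "mt_config_error")
  }
  if (cfg$top_k < 1L) abort("`top_k` must be >= 1", class = "mt_config_error")
  if (cfg$n_perm < 1L) abort("`n_perm` must be >= 1", class = "mt_config_error")
  if (length(cfg$algorithms) < 1L) {
    abort("the prediction-algorithm complement must contain at least one tool",
          class = "mt_config_error")
  }
  invisible(cfg)
}

#' Read a configuration from a YAML file
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path Path to a YAML file whose keys are `mt_config()` arguments.
#' @return An `mt_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(mt_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(sprintf("unknown configuration key(s): %s", paste(bad, collapse = ", ")),
          class = "mt_config_error")
  }
  do.call(mt_config, raw)
}

#' @export
print.mt_config <- function(x, ...) {
  cat("<mt_config>\n")
  for (k in setdiff(names(x), "algorithms")) {
    cat(sprintf("  %-14s %s\n", k, format(x[[k]])))
  }
  cat(sprintf("  %-14s %s (n=%d)\n", "algorithms",
              paste(head(x$algorithms, 3), collapse = ","), length(x$algorithms)))
  invisible(x)
}

# provenance header written at the top of every TSV/JSON output
provenance_header <- function(cfg = NULL) {
  lines <- c(
    sprintf("# mirtev %s", as.character(utils::packageVersion("mirtev"))),
    sprintf("# generated %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  if (!is.null(cfg)) {
    flat <- cfg
    flat$algorithms <- paste(cfg$algorithms, collapse = ",")
    kv <- paste(names(flat), vapply(flat, function(v) paste(format(v), collapse = ","), ""),
                sep = "=", collapse = " ")
    lines <- c(lines, paste0("# config ", kv))
  }
  lines
}
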