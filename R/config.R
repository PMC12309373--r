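#' Workflow configuration
#'
#' Collects every tunable threshold of the cluster-anchored enrichment
#' workflow in one validated object. The defaults are the workflow's
#' reference settings: STRING-style interaction confidence 0.9, MCL
#' inflation 4, lower cluster size filter 4, FDR 0.05, biological-function
#' size window 5--500, and enrichment gene count filter 3.
#'
#' @param confidence_min Minimum interaction confidence score kept when
#'   building the PPI graph, on the 0--1 probability scale (STRING's own
#'   default is 0.4; high-confidence analyses use 0.9).
#' @param inflation MCL inflation exponent (> 1). Larger values give more,
#'   smaller clusters.
#' @param min_cluster_size Lower cluster size filter: clusters with fewer
#'   genes than this are dissolved into the lonely cluster.
#' @param fdr_alpha Benjamini-Hochberg FDR significance limit for
#'   over-representation results.
#' @param term_size_min,term_size_max Biological-function size filter:
#'   only terms whose background-restricted gene-set size falls in
#'   `[term_size_min, term_size_max]` are tested.
#' @param min_enrichment_genes Enrichment gene count filter: minimum number
#'   of query genes in the overlap for a significant term to be reported.
#'   Applied after FDR correction; it does not change the test family.
#' @param db_order Either `NULL` (databases processed for merging in
#'   descending order of background coverage) or an explicit character
#'   vector of database names.
#' @param quantile_prob Probability used for the per-cluster benchmark-dose
#'   summary quantile (0.25 = first quartile, the sensitivity metric).
#' @param seed Integer seed recorded in the configuration and used by any
#'   randomised step.
#' @param fish_use_driver_terms If `TRUE` (default) lonely-gene fishing
#'   matches annotations against each cluster's retained terms after the
#'   ontology driver-term filter; if `FALSE`, against the pre-filter
#'   retained terms.
#' @param pool_fished_bmd If `TRUE` (default) transcripts of fished genes
#'   contribute their benchmark doses to every cluster they joined.
#' @param mcl_expansion Expansion power of the MCL iteration (matrix power).
#' @param mcl_prune Entries of the column-stochastic matrix below this value
#'   are zeroed between iterations.
#' @param mcl_tol Convergence tolerance: iteration stops when the largest
#'   elementwise change falls below this value.
#' @param mcl_max_iter Maximum MCL iterations before a convergence error.
#'
#' @return A `fishnet_config` object (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$confidence_min
#' pipeline_config(confidence_min = 0.4, inflation = 2)
#' @export
pipeline_config <- function(confidence_min = 0.9,
                            inflation = 4,
                            min_cluster_size = 4,
                            fdr_alpha = 0.05,
                            term_size_min = 5,
                            term_size_max = 500,
                            min_enrichment_genes = 3,
                            db_order = NULL,
                            quantile_prob = 0.25,
                            seed = 1L,
                            fish_use_driver_terms = TRUE,
                            pool_fished_bmd = TRUE,
                            mcl_expansion = 2L,
                            mcl_prune = 1e-6,
                            mcl_tol = 1e-6,
                            mcl_max_iter = 200L) {
  chk_num <- function(x, name, lo = NULL, hi = NULL, strict_lo = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
      abort_config(sprintf("`%s` must be a single number", name))
    }
    if (!is.null(lo) && (if (strict_lo) x <= lo else x < lo)) {
      abort_config(sprintf("`%s` must be %s %s", name,
                           if (strict_lo) ">" else ">=", format(lo)))
    }
    if (!is.null(hi) && x > hi) {
      abort_config(sprintf("`%s` must be <= %s", name, format(hi)))
    }
    x
  }
  chk_num(confidence_min, "confidence_min", 0, 1)
  chk_num(inflation, "inflation", 1, strict_lo = TRUE)
  chk_num(min_cluster_size, "min_cluster_size", 1)
  chk_num(fdr_alpha, "fdr_alpha", 0, 1, strict_lo = TRUE)
  chk_num(term_size_min, "term_size_min", 1)
  chk_num(term_size_max, "term_size_max", 1)
  chk_num(min_enrichment_genes, "min_enrichment_genes", 1)
  chk_num(quantile_prob, "quantile_prob", 0, 1, strict_lo = TRUE)
  if (quantile_prob >= 1) abort_config("`quantile_prob` must be < 1")
  if (term_size_min > term_size_max) {
    abort_config("`term_size_min` must be <= `term_size_max`")
  }
  if (!is.null(db_order) && !is.character(db_order)) {
    abort_config("`db_order` must be NULL or a character vector of database names")
  }
  chk_num(mcl_expansion, "mcl_expansion", 2)
  chk_num(mcl_prune, "mcl_prune", 0)
  chk_num(mcl_tol, "mcl_tol", 0, strict_lo = TRUE)
  chk_num(mcl_max_iter, "mcl_max_iter", 1)

  structure(
    list(
      confidence_min = confidence_min,
      inflation = inflation,
      min_cluster_size = as.integer(min_cluster_size),
      fdr_alpha = fdr_alpha,
      term_size_min = as.integer(term_size_min),
      term_size_max = as.integer(term_size_max),
      min_enrichment_genes = as.integer(min_enrichment_genes),
      db_order = db_order,
      quantile_prob = quantile_prob,
      seed = as.integer(seed),
      fish_use_driver_terms = isTRUE(fish_use_driver_terms),
      pool_fished_bmd = isTRUE(pool_fished_bmd),
      mcl_expansion = as.integer(mcl_expansion),
      mcl_prune = mcl_prune,
      mcl_tol = mcl_tol,
      mcl_max_iter = as.integer(mcl_max_iter)
    ),
    class = "fishnet_config"
  )
}

#' @export
print.fishnet_config <- function(x, ...) {
  cat("<fishnet_config>\n")
  cat(sprintf("  PPI confidence >= %.2f | MCL inflation %.1f | cluster size >= %d\n",
              x$confidence_min, x$inflation, x$min_cluster_size))
  cat(sprintf("  ORA: FDR <= %.3g, term size %d-%d, overlap >= %d\n",
              x$fdr_alpha, x$term_size_min, x$term_size_max,
              x$min_enrichment_genes))
  cat(sprintf("  BMD summary quantile: %.2f | seed %d\n",
              x$quantile_prob, x$seed))
  invisible(x)
}
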