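# One-tailed hypergeometric over-representation testing with BH FDR
# control, the workflow's three filters (term size window, FDR limit,
# enrichment gene count) and a most-specific-term redundancy filter over
# an ontology DAG.

empty_enrichment <- function() {
  tibble::tibble(
    query_id = character(), db_name = character(),
    term_id = character(), term_name = character(),
    p_raw = double(), q_fdr = double(),
    k_overlap = integer(), n_query = integer(),
    K_term_bg = integer(), N_background = integer(),
    intersection = character(), driver = logical()
  )
}

#' Upper-tail hypergeometric probability
#'
#' Probability of observing an overlap of at least `k` genes between a
#' query of size `n` and a term annotating `K` of the `N` universe genes,
#' i.e. `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` — the one-tailed
#' Fisher test of over-representation.
#'
#' @param k Observed overlap (`0 <= k <= min(n, K)`).
#' @param n Query size.
#' @param K Term size within the universe.
#' @param N Universe size.
#' @return The upper-tail probability.
#' @examples
#' hypergeom_p(4, 4, 5, 10)  # 1/42
#' @export
hypergeom_p <- function(k, n, K, N) {
  if (any(is.na(c(k, n, K, N)))) abort_domain("hypergeom_p: NA argument")
  if (k < 0 || n < 0 || K < 0 || N < 0 || n > N || K > N || k > min(n, K)) {
    abort_domain(sprintf(
      "hypergeom_p: invalid arguments k=%s n=%s K=%s N=%s (need 0 <= k <= min(n, K) and n, K <= N)",
      k, n, K, N))
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with the input and capped at 1.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort_domain("bh_adjust: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis of one query against one collection
#'
#' Tests every term of `collection` whose background-restricted size falls
#' in the configured window (`term_size_min`--`term_size_max`; terms
#' outside the window are never tested and never enter the FDR family)
#' for over-representation in `query`. The universe is the set of
#' background genes annotated anywhere in the collection. BH correction is
#' applied across all tested terms of this (query, database) pair; results
#' are retained when `q_fdr <= fdr_alpha` and the overlap has at least
#' `min_enrichment_genes` genes (the count filter is applied after FDR and
#' does not shrink the family).
#'
#' @param query Character vector of gene ids (subset of the background).
#' @param collection A `gene_set_collection`.
#' @param lists A `gene_lists` object (supplies the background).
#' @param cfg A [pipeline_config()].
#' @param query_id Label stored in the results (cluster id, `"lonely"`,
#'   or `"standard"`).
#' @return A tibble of retained enrichment results (possibly empty), one
#'   row per term, sorted by `q_fdr` then `term_id`.
#' @export
ora_query <- function(query, collection, lists, cfg = pipeline_config(),
                      query_id = "query") {
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(lists, "gene_lists"))
  query <- unique(query)
  bad <- setdiff(query, lists$background)
  if (length(bad) > 0) {
    abort_domain(sprintf("query gene(s) outside the background: %s",
                         paste(utils::head(bad, 5), collapse = ", ")))
  }
  universe <- collection$annotated_bg
  N <- length(universe)
  q_in <- intersect(query, universe)
  n <- length(q_in)
  testable <- names(collection$terms)[
    collection$bg_sizes >= cfg$term_size_min &
      collection$bg_sizes <= cfg$term_size_max]
  if (n == 0 || length(testable) == 0) {
    if (length(query) == 0) message(sprintf("empty query `%s`: no tests run", query_id))
    return(empty_enrichment())
  }

  rows <- purrr::map_dfr(testable, function(id) {
    term <- collection$terms[[id]]
    inter <- intersect(q_in, term$genes)
    K <- unname(collection$bg_sizes[[id]])
    tibble::tibble(
      term_id = id, term_name = term$name,
      p_raw = hypergeom_p(length(inter), n, K, N),
      k_overlap = length(inter), K_term_bg = K,
      intersection = collapse_genes(inter)
    )
  })
  rows$q_fdr <- bh_adjust(rows$p_raw)
  out <- rows[rows$q_fdr <= cfg$fdr_alpha &
                rows$k_overlap >= cfg$min_enrichment_genes, , drop = FALSE]
  if (nrow(out) == 0) return(empty_enrichment())
  out <- tibble::tibble(
    query_id = query_id, db_name = collection$db_name,
    term_id = out$term_id, term_name = out$term_name,
    p_raw = out$p_raw, q_fdr = out$q_fdr,
    k_overlap = as.integer(out$k_overlap), n_query = as.integer(n),
    K_term_bg = as.integer(out$K_term_bg), N_background = as.integer(N),
    intersection = out$intersection, driver = TRUE
  )
  dplyr::arrange(out, q_fdr, term_id)
}

#' Keep only the most specific retained terms of an ontology
#'
#' Redundancy filter over retained enrichment results: within each
#' (query, database) group, a term is demoted (`driver = FALSE`) when one
#' of its retained descendants in the ontology DAG is also present, so only
#' the deepest, most specific representatives along each ancestry survive.
#' Terms not covered by the ontology are untouched. This is an
#' elim-flavoured approximation of topology-aware driver-term
#' highlighting.
#'
#' @param results Enrichment tibble (as from [ora_query()]).
#' @param ontology Tibble of `child`, `parent` edges over term ids
#'   (see [read_ontology_edges()]); must be a DAG.
#' @return The driver rows of `results` (with `driver = TRUE`).
#' @export
driver_filter <- function(results, ontology) {
  if (nrow(results) == 0) return(results)
  stopifnot(all(c("child", "parent") %in% names(ontology)))
  g <- igraph::graph_from_data_frame(ontology[, c("child", "parent")],
                                     directed = TRUE)
  if (!igraph::is_dag(g)) abort_input("ontology edges contain a cycle; expected a DAG")
  vnames <- igraph::V(g)$name

  results$driver <- TRUE
  groups <- split(seq_len(nrow(results)),
                  paste(results$query_id, results$db_name, sep = "\r"))
  for (idx in groups) {
    terms <- results$term_id[idx]
    present <- terms[terms %in% vnames]
    if (length(present) < 2) next
    # ancestors of each retained term (excluding itself); any retained
    # ancestor loses driver status
    for (t in present) {
      anc <- setdiff(names(igraph::subcomponent(g, t, mode = "out")), t)
      hit <- idx[results$term_id[idx] %in% anc]
      results$driver[hit] <- FALSE
    }
  }
  results[results$driver, , drop = FALSE]
}
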