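# Independent oracles and in-code fixture builders shared across tests.

# Exact hypergeometric upper tail by direct enumeration of outcome counts
# (binomial coefficients), independent of stats::phyper.
hyper_tail_oracle <- function(k, n, K, N) {
  if (k == 0) return(1)
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Literal enumeration over all size-n draws (tiny N only).
hyper_tail_bruteforce <- function(k, n, K, N) {
  universe <- seq_len(N)
  hits <- seq_len(K)
  draws <- utils::combn(universe, n)
  mean(colSums(matrix(draws %in% hits, nrow = n)) >= k)
}

# Direct Benjamini-Hochberg step-up: adj_(i) = min_{j >= i} p_(j) * m / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(ranked[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Order-statistic linear interpolation quantile, written out by hand.
quantile_oracle <- function(x, prob) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * prob
  lo <- floor(h)
  if (lo + 1 >= n) return(x[n])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

# Connected components of an undirected edge tibble, as sorted gene sets.
components_oracle <- function(edges, nodes = NULL) {
  nodes <- nodes %||% sort(unique(c(edges$node_a, edges$node_b)), method = "radix")
  g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                     directed = FALSE, vertices = nodes)
  memb <- igraph::components(g)$membership
  unname(lapply(split(names(memb), memb), function(x) sort(x, method = "radix")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- in-code object builders ------------------------------------------------

make_lists <- function(background, deregulated, bmd = NULL, trend = NULL,
                       regulator = NULL) {
  background <- sort(background, method = "radix")
  n <- length(background)
  tr <- tibble::tibble(
    transcript_id = paste0("t_", background),
    gene_id = background,
    gene_name = NA_character_,
    bmd = if (is.null(bmd)) rep(NA_real_, n) else unname(bmd[background]),
    bmd_ci_low = NA_real_, bmd_ci_high = NA_real_,
    trend = if (is.null(trend)) rep(NA_character_, n) else unname(trend[background]),
    model = NA_character_,
    deregulated = background %in% deregulated,
    regulator = if (is.null(regulator)) rep("none", n)
                else unname(regulator[background])
  )
  tr$regulator[is.na(tr$regulator)] <- "none"
  structure(list(background = background,
                 deregulated = sort(deregulated, method = "radix"),
                 transcripts = tr),
            class = "gene_lists")
}

make_collection <- function(db_name, term_genes, background,
                            term_names = NULL) {
  terms <- lapply(names(term_genes), function(id) {
    list(name = if (is.null(term_names)) id else term_names[[id]],
         genes = sort(term_genes[[id]], method = "radix"))
  })
  names(terms) <- names(term_genes)
  fishnet:::new_gene_set_collection(db_name, terms, background)
}

make_graph <- function(edges, confidence_min = 0.9) {
  nodes <- sort(unique(c(edges$node_a, edges$node_b)), method = "radix")
  structure(list(nodes = nodes, edges = edges, confidence_min = confidence_min),
            class = "ppi_graph")
}

clique_edges <- function(nodes, score = 0.95) {
  p <- utils::combn(nodes, 2)
  tibble::tibble(node_a = p[1, ], node_b = p[2, ],
                 score = rep_len(score, ncol(p)))
}

make_cluster <- function(id, genes, enriched = NULL, provenance = "mcl") {
  fishnet:::new_cluster(id, genes, provenance = provenance,
                        enriched = enriched)
}

# minimal retained-enrichment rows for workflow tests
enr_rows <- function(query_id, db, term_ids) {
  tibble::tibble(
    query_id = query_id, db_name = db, term_id = term_ids,
    term_name = term_ids, p_raw = 1e-4, q_fdr = 1e-3,
    k_overlap = 3L, n_query = 5L, K_term_bg = 10L, N_background = 100L,
    intersection = "", driver = TRUE
  )
}
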