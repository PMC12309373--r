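# PPI graph construction and Markov Cluster (MCL) partitioning of the
# deregulated gene set. The MCL implementation is internal: weighted
# adjacency with self-loops, column normalisation, then alternating
# expansion (matrix power) and inflation (elementwise power with
# re-normalisation) with pruning until the matrix is stable; attractor
# systems of the limit matrix are read out as clusters.

#' Build the confidence-thresholded PPI graph over deregulated genes
#'
#' Keeps only edges whose two endpoints are deregulated genes and whose
#' confidence score is at least `cfg$confidence_min`. Deregulated genes
#' with no surviving edge are absent from the graph and later fall into
#' the lonely cluster.
#'
#' @param lists A `gene_lists` object.
#' @param edges Edge tibble from [read_ppi_edges()].
#' @param cfg A [pipeline_config()].
#' @return A `ppi_graph` object (`nodes`, `edges`, `confidence_min`).
#' @export
build_graph <- function(lists, edges, cfg = pipeline_config()) {
  stopifnot(inherits(lists, "gene_lists"))
  drg <- lists$deregulated
  kept <- edges[edges$node_a %in% drg & edges$node_b %in% drg &
                  edges$score >= cfg$confidence_min, , drop = FALSE]
  nodes <- sort_c(unique(c(kept$node_a, kept$node_b)))
  structure(
    list(nodes = nodes,
         edges = tibble::as_tibble(kept),
         confidence_min = cfg$confidence_min),
    class = "ppi_graph"
  )
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("<ppi_graph> %d nodes, %d edges (confidence >= %.2f)\n",
              length(x$nodes), nrow(x$edges), x$confidence_min))
  invisible(x)
}

#' Partition a PPI graph with the Markov Cluster algorithm
#'
#' Deterministic MCL: the weighted adjacency matrix gets a self-loop per
#' node equal to its maximum incident edge weight (keeps the random walk
#' well-conditioned), columns are normalised to a stochastic matrix, and
#' the iteration alternates expansion (`M^e`, default squaring) with
#' inflation (elementwise power `cfg$inflation`, re-normalised), zeroing
#' entries below `cfg$mcl_prune`. Convergence is declared when the largest
#' elementwise change drops below `cfg$mcl_tol`; exceeding
#' `cfg$mcl_max_iter` raises a convergence error reporting the residual.
#' Attractors (nodes retaining mass on the diagonal) define the clusters;
#' in the rare case of a node attracted by two systems it is assigned to
#' the larger cluster, ties going to the cluster with the lexicographically
#' smallest member.
#'
#' @param graph A `ppi_graph`.
#' @param cfg A [pipeline_config()]; `inflation` controls granularity.
#' @return A list of character vectors, one per cluster, forming a
#'   partition of `graph$nodes`. Cells are sorted internally and ordered
#'   by decreasing size (ties by smallest member id).
#' @export
mcl_cluster <- function(graph, cfg = pipeline_config()) {
  stopifnot(inherits(graph, "ppi_graph"))
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0) return(list())

  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ia <- match(graph$edges$node_a, nodes)
  ib <- match(graph$edges$node_b, nodes)
  A[cbind(ia, ib)] <- graph$edges$score
  A[cbind(ib, ia)] <- graph$edges$score
  selfw <- apply(A, 1, max)
  selfw[selfw == 0] <- 1  # isolated node (self-loop-only graph)
  diag(A) <- selfw

  normalise <- function(M) sweep(M, 2, colSums(M), "/")
  M <- normalise(A)
  converged <- FALSE
  residual <- NA_real_
  for (iter in seq_len(cfg$mcl_max_iter)) {
    Mexp <- M
    for (e in seq_len(cfg$mcl_expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp ^ cfg$inflation
    Minf[Minf < cfg$mcl_prune] <- 0
    cs <- colSums(Minf)
    if (any(cs == 0)) {
      # pruning emptied a column: fall back to the dominant pre-prune entry
      for (j in which(cs == 0)) {
        i <- which.max(Mexp[, j])
        Minf[i, j] <- 1
      }
      cs <- colSums(Minf)
    }
    Mnew <- sweep(Minf, 2, cs, "/")
    residual <- max(abs(Mnew - M))
    M <- Mnew
    if (residual < cfg$mcl_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort_convergence(sprintf(
      "MCL did not converge in %d iterations (residual %.3g)",
      cfg$mcl_max_iter, residual))
  }

  support <- M > cfg$mcl_prune
  attractors <- which(diag(M) > cfg$mcl_prune)
  if (length(attractors) == 0) attractors <- seq_len(n)

  # attractor systems: connected components of the symmetrised support
  # restricted to attractor rows/columns
  sub <- support[attractors, attractors, drop = FALSE]
  sys_graph <- igraph::graph_from_adjacency_matrix(sub | t(sub), mode = "undirected")
  sys_id <- igraph::components(sys_graph)$membership

  # provisional (possibly overlapping) membership of every node
  memb <- vector("list", max(sys_id))
  for (s in seq_len(max(sys_id))) {
    rows <- attractors[sys_id == s]
    cols <- which(colSums(support[rows, , drop = FALSE]) > 0)
    memb[[s]] <- union(cols, rows)
  }
  covered <- sort(unique(unlist(memb)))
  leftover <- setdiff(seq_len(n), covered)
  for (j in leftover) {  # numerical stragglers: follow the dominant flow
    i <- which.max(M[, j])
    s <- which(vapply(memb, function(m) i %in% m, logical(1)))[1]
    if (is.na(s)) memb <- c(memb, list(j)) else memb[[s]] <- c(memb[[s]], j)
  }

  # resolve overlaps: larger cluster wins, tie -> smallest member id
  sizes <- lengths(memb)
  smallest <- vapply(memb, function(m) sort_c(nodes[m])[1], character(1))
  pref <- order(-sizes, smallest, method = "radix")
  assigned <- rep(NA_integer_, n)
  for (s in pref) {
    free <- memb[[s]][is.na(assigned[memb[[s]]])]
    assigned[free] <- s
  }

  cells <- split(nodes, assigned)
  cells <- lapply(cells, sort_c)
  sizes <- lengths(cells)
  first <- vapply(cells, `[`, character(1), 1)
  cells[order(-sizes, first, method = "radix")]
}

#' Apply the lower cluster size filter and collect lonely genes
#'
#' Partition cells with at least `cfg$min_cluster_size` genes become
#' retained clusters (ids `c1`, `c2`, ... in order of decreasing size,
#' ties by smallest member gene id); every other partitioned gene, plus
#' deregulated genes absent from the graph, forms the lonely cluster.
#'
#' @param lists A `gene_lists` object.
#' @param partition Output of [mcl_cluster()].
#' @param cfg A [pipeline_config()].
#' @return A `clustering` object with `clusters` (named list) and `lonely`
#'   (character vector).
#' @export
partition_and_filter <- function(lists, partition, cfg = pipeline_config()) {
  stopifnot(inherits(lists, "gene_lists"))
  sizes <- lengths(partition)
  keep <- sizes >= cfg$min_cluster_size
  kept <- partition[keep]
  if (length(kept) > 0) {
    first <- vapply(kept, `[`, character(1), 1)
    kept <- kept[order(-lengths(kept), first, method = "radix")]
  }
  clusters <- list()
  for (i in seq_along(kept)) {
    id <- paste0("c", i)
    clusters[[id]] <- new_cluster(id, kept[[i]], provenance = "mcl")
  }
  in_clusters <- unlist(lapply(clusters, `[[`, "genes"), use.names = FALSE)
  lonely <- sort_c(setdiff(lists$deregulated, in_clusters))
  new_clustering(clusters, lonely)
}

new_cluster <- function(id, genes, provenance = "mcl",
                        merged_from = character(0), fished = character(0),
                        enriched = NULL) {
  stopifnot(length(genes) > 0)
  structure(
    list(cluster_id = id, genes = sort_c(genes), provenance = provenance,
         merged_from = merged_from, fished = fished,
         enriched = enriched %||% empty_enrichment()),
    class = "fishnet_cluster"
  )
}

new_clustering <- function(clusters, lonely) {
  structure(list(clusters = clusters, lonely = sort_c(lonely)),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$genes), integer(1))
  cat(sprintf("<clustering> %d cluster(s) (%d genes) + %d lonely gene(s)\n",
              length(x$clusters), sum(sizes), length(x$lonely)))
  invisible(x)
}

#' Export a clustering as a two-column table
#'
#' @param clustering A `clustering` object.
#' @return A tibble `gene_id`, `cluster_id` (lonely genes carry
#'   `"lonely"`), one row per membership; fished genes appear once per
#'   cluster joined.
#' @export
clustering_table <- function(clustering) {
  rows <- purrr::map_dfr(clustering$clusters, function(cl) {
    tibble::tibble(gene_id = cl$genes, cluster_id = cl$cluster_id)
  })
  dplyr::bind_rows(rows,
                   tibble::tibble(gene_id = clustering$lonely,
                                  cluster_id = rep("lonely", length(clustering$lonely))))
}
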