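# Orchestration of the full workflow: cluster-wise ORA, merging of
# clusters that share enriched functions, lonely-gene fishing with the
# friendliness metric, enrichment of the residual lonely cluster, and the
# whole-list "standard" comparison run.

term_keys <- function(db, term_ids) paste(db, term_ids, sep = "\r")

cluster_term_keys <- function(cluster, db = NULL) {
  enr <- cluster$enriched
  if (is.null(enr) || nrow(enr) == 0) return(character(0))
  if (!is.null(db)) enr <- enr[enr$db_name == db, , drop = FALSE]
  unique(term_keys(enr$db_name, enr$term_id))
}

db_merge_order <- function(collections, cfg) {
  names(collections) <- vapply(collections, `[[`, character(1), "db_name")
  if (!is.null(cfg$db_order)) {
    missing <- setdiff(cfg$db_order, names(collections))
    if (length(missing) > 0) {
      abort_config(sprintf("db_order names unknown database(s): %s",
                           paste(missing, collapse = ", ")))
    }
    return(cfg$db_order)
  }
  cov <- vapply(collections, `[[`, integer(1), "coverage")
  names(collections)[order(-cov, names(collections), method = "radix")]
}

#' Merge clusters that share enriched biological functions
#'
#' Databases are processed one at a time, by default in descending order of
#' background coverage (or an explicit `cfg$db_order`). For each database a
#' sharing graph is built on the current clusters — an edge whenever two
#' clusters retain at least one common enriched term id from that
#' database — and every connected component of two or more clusters is
#' replaced by a merged cluster whose gene and enriched-term sets are the
#' unions of its members (provenance `"merged"`, constituents recorded in
#' `merged_from`). Merged clusters are not re-tested; the next database
#' operates on the updated clustering. The operation is idempotent.
#'
#' @param clustering A `clustering` whose clusters carry retained
#'   enrichment results.
#' @param collections List of `gene_set_collection`s (for coverage order).
#' @param cfg A [pipeline_config()].
#' @return The merged `clustering`.
#' @export
merge_clusters <- function(clustering, collections, cfg = pipeline_config()) {
  stopifnot(inherits(clustering, "clustering"))
  for (db in db_merge_order(collections, cfg)) {
    clusters <- clustering$clusters
    if (length(clusters) < 2) break
    ids <- names(clusters)
    keysets <- lapply(clusters, cluster_term_keys, db = db)
    # sharing graph: edge iff >= 1 common retained term of this database
    adj <- lapply(seq_along(ids), function(i) {
      if (length(keysets[[i]]) == 0) return(integer(0))
      which(vapply(keysets, function(k) length(intersect(k, keysets[[i]])) > 0,
                   logical(1)))
    })
    g <- igraph::graph_from_adj_list(adj, mode = "all")
    comp <- igraph::components(g)$membership
    new_clusters <- list()
    for (s in sort(unique(comp))) {
      members <- ids[comp == s]
      if (length(members) == 1) {
        cl <- clusters[[members]]
        new_clusters[[cl$cluster_id]] <- cl
      } else {
        members <- members[order_ids(members)]
        genes <- sort_c(unique(unlist(lapply(clusters[members], `[[`, "genes"))))
        enr <- dplyr::bind_rows(lapply(clusters[members], `[[`, "enriched"))
        enr <- dplyr::arrange(enr, db_name, q_fdr, term_id)
        from <- sort_c(unique(unlist(lapply(members, function(m) {
          prev <- clusters[[m]]$merged_from
          if (length(prev) > 0) prev else m
        }))))
        fished <- sort_c(unique(unlist(lapply(clusters[members], `[[`, "fished"))))
        id <- paste0("m", members[1])
        new_clusters[[id]] <- new_cluster(id, genes, provenance = "merged",
                                          merged_from = from, fished = fished,
                                          enriched = enr)
      }
    }
    ord <- order(-vapply(new_clusters, function(cl) length(cl$genes), integer(1)),
                 vapply(new_clusters, function(cl) cl$genes[1], character(1)),
                 method = "radix")
    clustering$clusters <- new_clusters[ord]
  }
  clustering
}

# gene -> annotation keys (db \r term_id), restricted to terms eligible for
# enrichment (size window against the background)
annotation_keys <- function(collections, cfg) {
  out <- list()
  for (coll in collections) {
    eligible <- names(coll$terms)[coll$bg_sizes >= cfg$term_size_min &
                                    coll$bg_sizes <= cfg$term_size_max]
    for (id in eligible) {
      key <- term_keys(coll$db_name, id)
      for (gene in coll$terms[[id]]$genes) {
        out[[gene]] <- c(out[[gene]], key)
      }
    }
  }
  out
}

#' Fish lonely genes into functionally matching clusters
#'
#' A lonely gene annotated (in any supplied collection, restricted to
#' terms eligible for enrichment) to at least one term retained as
#' enriched in a cluster is incorporated into that cluster; it may join
#' several clusters, and from this step on clusters are allowed to
#' overlap. Joined clusters take provenance `"expanded"`; fished genes
#' leave the lonely cluster. The friendliness of a fished gene is the
#' number of clusters it joined.
#'
#' @param clustering A post-merge `clustering` with retained enrichments.
#' @param collections List of `gene_set_collection`s.
#' @param cfg A [pipeline_config()].
#' @return A list: `clustering` (updated) and `fishing`, a tibble with one
#'   row per fished gene (`gene_id`, `friendliness`, `joined_clusters` and
#'   `via_terms` as list-columns).
#' @export
fish_lonely <- function(clustering, collections, cfg = pipeline_config()) {
  stopifnot(inherits(clustering, "clustering"))
  ann <- annotation_keys(collections, cfg)
  cluster_keys <- lapply(clustering$clusters, cluster_term_keys)

  records <- list()
  joined_by_cluster <- stats::setNames(
    vector("list", length(clustering$clusters)), names(clustering$clusters))
  for (gene in clustering$lonely) {
    gkeys <- ann[[gene]]
    if (is.null(gkeys)) next
    via <- list()
    for (cid in names(cluster_keys)) {
      shared <- intersect(gkeys, cluster_keys[[cid]])
      if (length(shared) > 0) {
        via[[cid]] <- sort_c(sub("\r", ":", shared, fixed = TRUE))
        joined_by_cluster[[cid]] <- c(joined_by_cluster[[cid]], gene)
      }
    }
    if (length(via) > 0) {
      records[[gene]] <- tibble::tibble(
        gene_id = gene,
        friendliness = length(via),
        joined_clusters = list(names(via)),
        via_terms = list(via)
      )
    }
  }

  fished_genes <- names(records)
  for (cid in names(joined_by_cluster)) {
    newg <- joined_by_cluster[[cid]]
    if (length(newg) == 0) next
    cl <- clustering$clusters[[cid]]
    cl$genes <- sort_c(union(cl$genes, newg))
    cl$fished <- sort_c(union(cl$fished, newg))
    cl$provenance <- "expanded"
    clustering$clusters[[cid]] <- cl
  }
  clustering$lonely <- sort_c(setdiff(clustering$lonely, fished_genes))

  fishing <- if (length(records) > 0) {
    dplyr::bind_rows(records[sort_c(fished_genes)])
  } else {
    tibble::tibble(gene_id = character(), friendliness = integer(),
                   joined_clusters = list(), via_terms = list())
  }
  list(clustering = clustering, fishing = fishing)
}

#' Run the full cluster-anchored enrichment workflow
#'
#' Executes, in order: PPI graph construction, MCL partitioning, the lower
#' cluster size filter, cluster-wise ORA per database (with the optional
#' ontology driver-term filter), merging of clusters sharing enriched
#' functions, lonely-gene fishing, and ORA of the residual lonely cluster.
#' A whole-list "standard" ORA is run alongside for comparison. Every step
#' is logged with its counts.
#'
#' @param lists A `gene_lists` object (optionally regulator-annotated).
#' @param edges PPI edge tibble from [read_ppi_edges()].
#' @param collections List of `gene_set_collection`s (one per database).
#' @param cfg A [pipeline_config()].
#' @param ontology Optional `child`/`parent` term-edge tibble enabling the
#'   driver-term redundancy filter.
#' @return A `fishnet_result` with `clustering`, `enrichments` (clusters +
#'   lonely + standard), `fishing`, `standard`, `config` and `log`.
#' @export
run_pipeline <- function(lists, edges, collections, cfg = pipeline_config(),
                         ontology = NULL) {
  stopifnot(inherits(lists, "gene_lists"))
  names(collections) <- vapply(collections, `[[`, character(1), "db_name")
  log <- character(0)
  note <- function(fmt, ...) {
    log[[length(log) + 1L]] <<- sprintf(fmt, ...)
  }
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("step `%s` failed: %s", name, conditionMessage(e)),
                   class = class(e)[1], parent = e)
    })
  }

  note("input: %d background genes, %d deregulated genes, %d transcripts",
       length(lists$background), length(lists$deregulated),
       nrow(lists$transcripts))

  if (length(lists$deregulated) == 0) {
    note("deregulated list empty: pipeline short-circuited")
    return(new_result(new_clustering(list(), character(0)),
                      empty_enrichment(),
                      fish_lonely(new_clustering(list(), character(0)),
                                  collections, cfg)$fishing,
                      empty_enrichment(), cfg, log))
  }

  graph <- step("build_graph", build_graph(lists, edges, cfg))
  note("graph: %d nodes, %d edges at confidence >= %.2f",
       length(graph$nodes), nrow(graph$edges), cfg$confidence_min)

  partition <- step("mcl_cluster", mcl_cluster(graph, cfg))
  note("mcl: %d raw cluster(s) at inflation %.1f", length(partition),
       cfg$inflation)

  clustering <- step("partition_and_filter",
                     partition_and_filter(lists, partition, cfg))
  note("size filter >= %d: %d cluster(s) retained (%d genes), %d lonely",
       cfg$min_cluster_size, length(clustering$clusters),
       sum(vapply(clustering$clusters, function(cl) length(cl$genes), integer(1))),
       length(clustering$lonely))

  clustering$clusters <- step("cluster_ora", lapply(clustering$clusters, function(cl) {
    res <- dplyr::bind_rows(lapply(collections, function(coll) {
      ora_query(cl$genes, coll, lists, cfg, query_id = cl$cluster_id)
    }))
    if (!is.null(ontology) && nrow(res) > 0) res <- driver_filter(res, ontology)
    cl$enriched <- res
    cl
  }))
  n_enr <- sum(vapply(clustering$clusters, function(cl) nrow(cl$enriched), integer(1)))
  note("cluster-wise ORA: %d retained enrichment(s) across %d database(s)",
       n_enr, length(collections))

  pre_merge <- length(clustering$clusters)
  clustering <- step("merge_clusters", merge_clusters(clustering, collections, cfg))
  note("merge: %d -> %d cluster(s)", pre_merge, length(clustering$clusters))

  fished <- step("fish_lonely", fish_lonely(clustering, collections, cfg))
  clustering <- fished$clustering
  note("fishing: %d gene(s) fished, %d remaining lonely",
       nrow(fished$fishing), length(clustering$lonely))

  lonely_query <- intersect(clustering$lonely, lists$background)
  lonely_enr <- step("lonely_ora", dplyr::bind_rows(lapply(collections, function(coll) {
    ora_query(lonely_query, coll, lists, cfg, query_id = "lonely")
  })))
  if (!is.null(ontology) && nrow(lonely_enr) > 0) {
    lonely_enr <- driver_filter(lonely_enr, ontology)
  }
  note("lonely-cluster ORA: %d retained enrichment(s)", nrow(lonely_enr))

  standard <- step("standard_ora",
                   run_standard(lists, collections, cfg, ontology = ontology))
  note("standard whole-list ORA: %d retained enrichment(s)", nrow(standard))

  cluster_enr <- dplyr::bind_rows(lapply(clustering$clusters, `[[`, "enriched"))
  enrichments <- dplyr::bind_rows(cluster_enr, lonely_enr, standard)
  new_result(clustering, enrichments, fished$fishing, standard, cfg, log)
}

new_result <- function(clustering, enrichments, fishing, standard, cfg, log) {
  structure(
    list(clustering = clustering, enrichments = enrichments,
         fishing = fishing, standard = standard, config = cfg, log = log),
    class = "fishnet_result"
  )
}

#' @export
print.fishnet_result <- function(x, ...) {
  cat("<fishnet_result>\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}

#' Whole-list "standard" over-representation analysis
#'
#' The conventional approach the cluster-anchored workflow is compared
#' against: one ORA per database with the entire deregulated gene list as
#' the query, under identical filters. Results carry `query_id =
#' "standard"`.
#'
#' @param lists A `gene_lists` object.
#' @param collections List of `gene_set_collection`s.
#' @param cfg A [pipeline_config()].
#' @param ontology Optional ontology edges for the driver-term filter.
#' @return Enrichment tibble of retained standard results.
#' @export
run_standard <- function(lists, collections, cfg = pipeline_config(),
                         ontology = NULL) {
  res <- dplyr::bind_rows(lapply(collections, function(coll) {
    ora_query(lists$deregulated, coll, lists, cfg, query_id = "standard")
  }))
  if (!is.null(ontology) && nrow(res) > 0) res <- driver_filter(res, ontology)
  res
}

#' Compare standard and cluster-anchored gene involvement
#'
#' Derives the gene sets each approach brings into enriched biological
#' functions: for the standard run, genes in the intersection of at least
#' one retained whole-list enrichment; for the anchored run, members of
#' final (merged/expanded) clusters plus genes in retained lonely-cluster
#' enrichments. Reports the overlap counts of the two sets against the
#' deregulated list.
#'
#' @param result A `fishnet_result`.
#' @param lists The `gene_lists` the pipeline ran on.
#' @return A one-row tibble of counts (`n_deregulated`, `n_standard`,
#'   `n_anchored`, `n_shared`, `n_standard_only`, `n_anchored_only`,
#'   `n_neither`), with the two gene sets attached as attributes
#'   `genes_standard` and `genes_anchored`.
#' @export
compare_workflows <- function(result, lists) {
  stopifnot(inherits(result, "fishnet_result"))
  split_members <- function(x) unique(unlist(strsplit(x, ";", fixed = TRUE)))
  std_genes <- if (nrow(result$standard) > 0) {
    sort_c(split_members(result$standard$intersection))
  } else character(0)
  cluster_genes <- unique(unlist(lapply(result$clustering$clusters, `[[`, "genes")))
  lonely_rows <- result$enrichments[result$enrichments$query_id == "lonely", ,
                                    drop = FALSE]
  lonely_genes <- if (nrow(lonely_rows) > 0) split_members(lonely_rows$intersection)
                  else character(0)
  anch_genes <- sort_c(union(cluster_genes, lonely_genes))
  drg <- lists$deregulated
  out <- tibble::tibble(
    n_deregulated = length(drg),
    n_standard = length(std_genes),
    n_anchored = length(anch_genes),
    n_shared = length(intersect(std_genes, anch_genes)),
    n_standard_only = length(setdiff(std_genes, anch_genes)),
    n_anchored_only = length(setdiff(anch_genes, std_genes)),
    n_neither = length(setdiff(drg, union(std_genes, anch_genes)))
  )
  attr(out, "genes_standard") <- std_genes
  attr(out, "genes_anchored") <- anch_genes
  out
}
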