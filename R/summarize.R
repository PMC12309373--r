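# Per-cluster dose-response summaries: benchmark-dose quantiles, trend
# composition, regulator counts and the sensitivity ranking of the final
# clusters.

#' Benchmark-dose summary quantile of a cluster
#'
#' Linear-interpolation sample quantile of a set of benchmark doses:
#' with `h = (n - 1) * prob`, the value interpolates between the order
#' statistics at positions `floor(h)` and `floor(h) + 1`. At `prob = 0.25`
#' this is the first quartile — the dose below which a quarter of the
#' cluster's transcript BMDs fall, used to rank clusters from most to
#' least sensitive.
#'
#' @param bmds Numeric vector of positive benchmark doses.
#' @param prob Probability in (0, 1).
#' @return The quantile, or `NA_real_` for an empty input.
#' @examples
#' cluster_bmd_quantile(c(1, 2, 3, 4, 5), 0.25)  # 2
#' @export
cluster_bmd_quantile <- function(bmds, prob = 0.25) {
  bmds <- bmds[!is.na(bmds)]
  if (length(bmds) == 0) return(NA_real_)
  if (!is.numeric(prob) || length(prob) != 1 || prob <= 0 || prob >= 1) {
    abort_domain("`prob` must be a single probability in (0, 1)")
  }
  unname(stats::quantile(bmds, probs = prob, type = 7, names = FALSE))
}

cluster_summary_row <- function(id, genes, provenance, fished, enriched,
                                transcripts, prob, pool_fished) {
  use_genes <- if (pool_fished) genes else setdiff(genes, fished)
  tr <- transcripts[transcripts$gene_id %in% use_genes & transcripts$deregulated, ,
                    drop = FALSE]
  bmds <- tr$bmd[!is.na(tr$bmd)]
  trend_n <- function(lvl) sum(!is.na(tr$trend) & tr$trend == lvl)
  terms <- if (nrow(enriched) > 0) {
    paste(sort_c(unique(paste0(enriched$db_name, ":", enriched$term_id))),
          collapse = ";")
  } else ""
  tibble::tibble(
    cluster_id = id,
    provenance = provenance,
    n_genes = length(genes),
    n_fished = length(fished),
    n_transcripts = nrow(tr),
    bmd_q25 = cluster_bmd_quantile(bmds, prob),
    n_bmd = length(bmds),
    n_inc = trend_n("inc"), n_dec = trend_n("dec"),
    n_bell = trend_n("bell"), n_U = trend_n("U"),
    n_regulators = length(unique(tr$gene_id[tr$regulator != "none"])),
    enriched_terms = terms,
    bmd_values = list(sort(bmds))
  )
}

#' Summarise the final clusters of a pipeline run
#'
#' One row per final cluster — including the lonely cluster — pooling the
#' benchmark doses of all transcripts whose gene belongs to the cluster
#' (transcript-level, so a gene with several modelled transcripts
#' contributes each of them; fished genes contribute to every cluster they
#' joined unless `cfg$pool_fished_bmd` is off). Rows are ordered by
#' ascending BMD quantile, most sensitive cluster first, clusters without
#' any BMD last. The standard-versus-anchored gene overlap counts are
#' attached as the `overlap` element.
#'
#' @param result A `fishnet_result`.
#' @param lists The `gene_lists` the pipeline ran on (supplies transcripts
#'   and dose-response metrics; without them the summary degrades to
#'   counts and terms).
#' @param cfg A [pipeline_config()].
#' @return A list with `summary` (tibble, one row per final cluster) and
#'   `overlap` (one-row tibble from [compare_workflows()]).
#' @export
build_summary <- function(result, lists, cfg = pipeline_config()) {
  stopifnot(inherits(result, "fishnet_result"), inherits(lists, "gene_lists"))
  tr <- lists$transcripts
  rows <- purrr::map_dfr(result$clustering$clusters, function(cl) {
    cluster_summary_row(cl$cluster_id, cl$genes, cl$provenance, cl$fished,
                        cl$enriched, tr, cfg$quantile_prob, cfg$pool_fished_bmd)
  })
  if (length(result$clustering$lonely) > 0) {
    lonely_enr <- result$enrichments[result$enrichments$query_id == "lonely", ,
                                     drop = FALSE]
    rows <- dplyr::bind_rows(rows, cluster_summary_row(
      "lonely", result$clustering$lonely, "lonely", character(0), lonely_enr,
      tr, cfg$quantile_prob, pool_fished = TRUE))
  }
  if (nrow(rows) > 0) {
    rows <- rows[order(is.na(rows$bmd_q25), rows$bmd_q25,
                       nchar(rows$cluster_id), rows$cluster_id,
                       method = "radix"), , drop = FALSE]
  }
  list(summary = rows, overlap = compare_workflows(result, lists))
}

#' Write the tabular outputs of a pipeline run
#'
#' Writes, into `dir`: `clusters.tsv` (gene-to-cluster memberships),
#' `enrichments.csv` (all retained results), `fishing.csv` (one row per
#' fished gene), `summary.csv` (one row per final cluster, sensitivity
#' ordered), `overlap.csv` (standard vs anchored gene counts) and
#' `log.txt` (step records). Output is deterministic: identical inputs,
#' configuration and seed give byte-identical files.
#'
#' @param result A `fishnet_result`.
#' @param lists The `gene_lists` the pipeline ran on.
#' @param cfg A [pipeline_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, lists, cfg = pipeline_config(), dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("clusters.tsv", "enrichments.csv", "fishing.csv",
                            "summary.csv", "overlap.csv", "log.txt"))
  readr::write_tsv(clustering_table(result$clustering), paths[1])
  readr::write_csv(result$enrichments, paths[2])
  fishing <- result$fishing
  fishing_flat <- tibble::tibble(
    gene_id = fishing$gene_id,
    friendliness = fishing$friendliness,
    joined_clusters = vapply(fishing$joined_clusters, paste, character(1),
                             collapse = ";"),
    via_terms = vapply(fishing$via_terms, function(v) {
      paste(vapply(names(v), function(cid) {
        paste0(cid, "=", paste(v[[cid]], collapse = "|"))
      }, character(1)), collapse = ";")
    }, character(1))
  )
  readr::write_csv(fishing_flat, paths[3])
  summ <- build_summary(result, lists, cfg)
  flat <- summ$summary
  flat$bmd_values <- vapply(flat$bmd_values, function(v) {
    paste(format(v, trim = TRUE, digits = 15), collapse = ";")
  }, character(1))
  readr::write_csv(flat, paths[4])
  readr::write_csv(summ$overlap, paths[5])
  writeLines(result$log, paths[6])
  invisible(paths)
}
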