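# Readers and writers for every external input: dose-response results,
# GMT gene-set collections, PPI edge lists, regulator annotations and
# ontology parent-child edges. Parsing is total: malformed input raises a
# typed condition, never a silent partial load.

TREND_LEVELS <- c("inc", "dec", "bell", "U")
REGULATOR_LEVELS <- c("TF", "CoTF", "none")

#' Read dose-response results into validated gene lists
#'
#' Reads the transcript-level results of an upstream dose-response (or any
#' other selection) analysis. The CSV must contain `transcript_id` and
#' `gene_id` columns; `gene_name`, `bmd`, `bmd_ci_low`, `bmd_ci_high`,
#' `trend` and `model` are optional. Membership of the deregulated list is
#' given either by a logical `deregulated` column (in which case the CSV
#' holds the full background) or by a separate one-column background file
#' (`gene_id` header) with every CSV row taken as deregulated.
#'
#' Transcripts with no gene mapping are reported and dropped from the
#' gene-level sets but kept in the count of unmapped transcripts
#' (`attr(x, "n_unmapped")`).
#'
#' @param path Path to the results CSV (UTF-8, `.` decimal separator).
#' @param background Optional path to a one-column background gene file.
#' @return A `gene_lists` object: `background` and `deregulated` gene-id
#'   vectors plus the `transcripts` tibble.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("transcript_id,gene_id,deregulated,bmd,trend",
#'              "t1,g1,TRUE,1.5,inc",
#'              "t2,g2,FALSE,,",
#'              "t3,g3,TRUE,4.2,dec"), tf)
#' lists <- read_dr_results(tf)
#' lists$deregulated
#' @export
read_dr_results <- function(path, background = NULL) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  for (col in c("transcript_id", "gene_id")) {
    if (!col %in% names(raw)) {
      abort_input(sprintf("missing required column `%s` in %s", col, path))
    }
  }
  dup <- raw$transcript_id[duplicated(raw$transcript_id)]
  if (length(dup) > 0) {
    abort_input(sprintf("duplicate transcript_id value(s): %s",
                        paste(unique(dup), collapse = ", ")))
  }

  num_col <- function(name) {
    if (!name %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    x <- raw[[name]]
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & x != "" & is.na(out)
    if (any(bad)) {
      abort_input(sprintf("non-numeric value in column `%s`: %s",
                          name, x[bad][1]))
    }
    out
  }
  chr_col <- function(name) {
    if (!name %in% names(raw)) return(rep(NA_character_, nrow(raw)))
    x <- raw[[name]]
    x[!is.na(x) & x == ""] <- NA_character_
    x
  }

  tr <- tibble::tibble(
    transcript_id = raw$transcript_id,
    gene_id = chr_col("gene_id"),
    gene_name = chr_col("gene_name"),
    bmd = num_col("bmd"),
    bmd_ci_low = num_col("bmd_ci_low"),
    bmd_ci_high = num_col("bmd_ci_high"),
    trend = chr_col("trend"),
    model = chr_col("model")
  )

  bad_trend <- setdiff(unique(tr$trend[!is.na(tr$trend)]), TREND_LEVELS)
  if (length(bad_trend) > 0) {
    abort_input(sprintf(
      "invalid trend label(s) %s; allowed labels are {%s}",
      paste(bad_trend, collapse = ", "), paste(TREND_LEVELS, collapse = ", ")))
  }
  if (any(!is.na(tr$bmd) & tr$bmd <= 0)) {
    abort_input("`bmd` values must be positive")
  }
  ci_bad <- !is.na(tr$bmd_ci_low) & !is.na(tr$bmd_ci_high) &
    tr$bmd_ci_low > tr$bmd_ci_high
  if (any(ci_bad)) {
    abort_input(sprintf("bmd_ci_low > bmd_ci_high for transcript %s",
                        tr$transcript_id[ci_bad][1]))
  }

  if ("deregulated" %in% names(raw)) {
    flag <- toupper(trimws(raw$deregulated)) %in% c("TRUE", "T", "1", "YES")
    tr$deregulated <- flag
  } else if (!is.null(background)) {
    tr$deregulated <- TRUE
  } else {
    abort_input("need either a `deregulated` column or a separate background file")
  }

  unmapped <- is.na(tr$gene_id)
  n_unmapped <- sum(unmapped)
  if (n_unmapped > 0) {
    message(sprintf("%d transcript(s) without a gene mapping excluded from gene-level sets",
                    n_unmapped))
  }
  mapped <- tr[!unmapped, ]

  if (!is.null(background)) {
    if (!file.exists(background)) {
      abort_input(sprintf("background file not found: %s", background))
    }
    bg_raw <- readr::read_csv(background,
                              col_types = readr::cols(.default = readr::col_character()),
                              progress = FALSE)
    if (!"gene_id" %in% names(bg_raw)) {
      abort_input("background file must have a `gene_id` column")
    }
    bg <- sort_c(unique(bg_raw$gene_id[!is.na(bg_raw$gene_id)]))
  } else {
    bg <- sort_c(unique(mapped$gene_id))
  }
  drg <- sort_c(unique(mapped$gene_id[mapped$deregulated]))

  missing_bg <- setdiff(drg, bg)
  if (length(missing_bg) > 0) {
    abort_consistency(sprintf(
      "deregulated gene(s) absent from the background list: %s",
      paste(utils::head(missing_bg, 5), collapse = ", ")))
  }
  bmd_not_drg <- mapped$gene_id[!is.na(mapped$bmd) & !mapped$deregulated]
  if (length(bmd_not_drg) > 0) {
    abort_consistency(sprintf(
      "transcript(s) carrying a BMD map to non-deregulated gene(s): %s",
      paste(utils::head(unique(bmd_not_drg), 5), collapse = ", ")))
  }

  tr$regulator <- "none"
  out <- structure(
    list(background = bg, deregulated = drg, transcripts = tr),
    class = "gene_lists"
  )
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' @export
print.gene_lists <- function(x, ...) {
  cat(sprintf("<gene_lists> %d background genes, %d deregulated, %d transcripts\n",
              length(x$background), length(x$deregulated), nrow(x$transcripts)))
  invisible(x)
}

#' Read a gene-set collection from a GMT file
#'
#' One term per line: `term_id <tab> description <tab> gene <tab> gene ...`.
#' Gene sets are stored as given; sizes used for testing (`bg_sizes`) and
#' the collection's `coverage` are restricted to the experimental
#' background, which is the over-representation universe. Genes absent from
#' the background stay in `terms` (they matter for annotation lookups) but
#' never enter a test count.
#'
#' @param path Path to the GMT file.
#' @param db_name Name of the source database (e.g. `"GO:BP"`, `"KEGG"`).
#' @param background Character vector of background gene ids.
#' @return A `gene_set_collection` object.
#' @export
read_gmt <- function(path, db_name, background) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  terms <- list()
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort_input(sprintf("GMT line %d has %d field(s); need term, description and >= 1 gene",
                          i, length(fields)))
    }
    id <- fields[1]
    if (id %in% names(terms)) {
      abort_input(sprintf("duplicate term id `%s` at GMT line %d", id, i))
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    terms[[id]] <- list(name = fields[2], genes = sort_c(genes))
  }
  new_gene_set_collection(db_name, terms, background)
}

new_gene_set_collection <- function(db_name, terms, background) {
  bg_sizes <- vapply(terms, function(t) length(intersect(t$genes, background)),
                     integer(1))
  all_genes <- as.character(unique(unlist(lapply(terms, `[[`, "genes"),
                                          use.names = FALSE)))
  annotated_bg <- sort_c(intersect(all_genes, background))
  structure(
    list(db_name = db_name, terms = terms, bg_sizes = bg_sizes,
         coverage = length(annotated_bg), annotated_bg = annotated_bg),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %s: %d terms, background coverage %d genes\n",
              x$db_name, length(x$terms), x$coverage))
  invisible(x)
}

#' Write a gene-set collection back to GMT
#'
#' Inverse of [read_gmt()]: re-reading the written file yields identical
#' term-to-gene mappings.
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$terms), function(id) {
    t <- collection$terms[[id]]
    paste(c(id, t$name, t$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PPI edge list
#'
#' Tab- or comma-separated with a header; the first three columns are taken
#' as node A, node B and the combined confidence score. Two score dialects
#' are accepted: probabilities in `[0, 1]` or STRING-style integers in
#' `[0, 1000]`. If any score exceeds 1 the whole column is divided by 1000
#' (reported via a message). Self-edges are dropped; duplicate undirected
#' pairs keep the maximum score.
#'
#' @param path Path to the edge file.
#' @return A tibble with columns `node_a`, `node_b`, `score`, one row per
#'   undirected edge, with `node_a < node_b` and rows sorted.
#' @export
read_ppi_edges <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = FALSE)
  if (ncol(raw) < 3) abort_input("edge list needs at least 3 columns (node, node, score)")
  a <- trimws(raw[[1]]); b <- trimws(raw[[2]])
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    abort_input("empty node name in edge list")
  }
  score <- suppressWarnings(as.numeric(raw[[3]]))
  if (any(is.na(score))) abort_input("non-numeric confidence score in edge list")
  if (any(score < 0 | score > 1000)) {
    abort_input("confidence scores must lie in [0, 1] or STRING-style [0, 1000]")
  }
  if (any(score > 1)) {
    message("scores > 1 detected: interpreting as STRING 0-1000 scale, dividing by 1000")
    score <- score / 1000
  }
  self <- a == b
  if (any(self)) {
    message(sprintf("dropped %d self-edge(s)", sum(self)))
    a <- a[!self]; b <- b[!self]; score <- score[!self]
  }
  node_a <- pmin(a, b)
  node_b <- pmax(a, b)
  edges <- tibble::tibble(node_a = node_a, node_b = node_b, score = score)
  edges <- dplyr::summarise(dplyr::group_by(edges, node_a, node_b),
                            score = max(score), .groups = "drop")
  dplyr::arrange(edges, node_a, node_b)
}

#' Flag transcription (co-)factors among the transcripts
#'
#' Reads a two-column file (`gene_id`, `class` with class `TF` or `CoTF`,
#' the shape of an AnimalTFDB-style download) and sets the `regulator`
#' field of every transcript record. The step is optional: when no file is
#' available all transcripts keep `regulator = "none"`. A gene listed as
#' both TF and CoTF is flagged TF (with a warning).
#'
#' @param lists A `gene_lists` object.
#' @param path Path to the regulator file.
#' @return The updated `gene_lists`.
#' @export
annotate_regulators <- function(lists, path) {
  stopifnot(inherits(lists, "gene_lists"))
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2) abort_input("regulator file needs gene_id and class columns")
  gene <- trimws(raw[[1]]); cls <- trimws(raw[[2]])
  bad <- setdiff(unique(cls), c("TF", "CoTF"))
  if (length(bad) > 0) {
    abort_input(sprintf("unknown regulator class label(s): %s (allowed: TF, CoTF)",
                        paste(bad, collapse = ", ")))
  }
  both <- intersect(gene[cls == "TF"], gene[cls == "CoTF"])
  if (length(both) > 0) {
    warning(sprintf("gene(s) listed as both TF and CoTF, keeping TF: %s",
                    paste(utils::head(both, 5), collapse = ", ")), call. = FALSE)
  }
  status <- stats::setNames(rep("none", length(unique(gene))), unique(gene))
  status[unique(gene[cls == "CoTF"])] <- "CoTF"
  status[unique(gene[cls == "TF"])] <- "TF"  # TF wins over CoTF

  reg <- status[lists$transcripts$gene_id]
  reg[is.na(reg)] <- "none"
  lists$transcripts$regulator <- unname(reg)
  lists
}

#' Read ontology parent-child edges
#'
#' Tab-separated `child <tab> parent` pairs over term ids, expected to form
#' a DAG (a cycle is a format error). Used by the driver-term redundancy
#' filter.
#'
#' @param path Path to the edge file (with header).
#' @return A tibble with columns `child`, `parent`.
#' @export
read_ontology_edges <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2) abort_input("ontology edge file needs child and parent columns")
  edges <- tibble::tibble(child = trimws(raw[[1]]), parent = trimws(raw[[2]]))
  if (any(!nzchar(edges$child)) || any(!nzchar(edges$parent))) {
    abort_input("empty term id in ontology edge file")
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (!igraph::is_dag(g)) abort_input("ontology edges contain a cycle; expected a DAG")
  edges
}
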