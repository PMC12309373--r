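# Deterministic synthetic fixture generator. Writes a complete input
# bundle (dose-response CSV, PPI edge list, GMT collection, regulator
# list, ontology edges) with planted, known-truth structure: functional
# modules as interaction-dense near-cliques annotated to planted terms,
# a set of lonely genes annotated so they can be fished, and per-module
# benchmark-dose windows giving the sensitivity ranking a known order.

#' Specify a synthetic input bundle
#'
#' The defaults describe the reference noiseless scenario: a 500-gene
#' background, 60 deregulated genes, three planted 8-gene modules (exact
#' cliques with edge scores above the 0.9 confidence threshold), five
#' lonely genes annotated to the planted terms so fishing can recover
#' them, and non-overlapping per-module benchmark-dose windows so the
#' cluster sensitivity ranking has an unambiguous expected order.
#'
#' @param seed Integer seed; the whole bundle is a deterministic function
#'   of the spec, and the same seed reproduces it byte for byte.
#' @param n_background,n_deregulated Background and deregulated gene
#'   counts.
#' @param module_sizes Integer vector, one planted module per entry.
#' @param term_extra Background-only genes added to each planted term (so
#'   planted terms are larger than their modules).
#' @param intra_edge_prob Probability of each within-module edge (1 =
#'   exact cliques).
#' @param edge_score_range Confidence score range of module edges; the
#'   default straddles nothing — it sits above the 0.9 threshold so
#'   planted modules survive graph construction by design.
#' @param n_lonely_annotated Deregulated genes kept off the network but
#'   annotated to planted terms (ground-truth fate `"fished"`).
#' @param noise_edges Number of random off-module edges, scored below the
#'   0.9 threshold (`noise_edge_score_range`).
#' @param noise_edge_score_range Score range of noise edges.
#' @param noise_terms Number of random gene-set terms drawn from the
#'   background.
#' @param noise_term_size_range Size range of noise terms.
#' @param bmd_windows Optional list of `c(low, high)` dose windows, one
#'   per module (defaults to non-overlapping windows `(1,2)`, `(4,8)`,
#'   `(16,32)`, ... most sensitive module first).
#' @param lonely_bmd_window Dose window of non-module deregulated genes.
#' @param trend_mix Named probabilities over trend classes
#'   `c(inc, dec, bell, U)`; the default mirrors a monotone-dominated
#'   dose-response screen.
#' @param with_ontology If `TRUE`, each planted term gets a broader parent
#'   term and a child-parent ontology edge, exercising the driver-term
#'   filter.
#' @param parent_extra Additional background-only genes per parent term.
#' @param n_tf,n_cotf Deregulated genes flagged TF / CoTF in the regulator
#'   file.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(seed = 1L,
                         n_background = 500L,
                         n_deregulated = 60L,
                         module_sizes = c(8L, 8L, 8L),
                         term_extra = 2L,
                         intra_edge_prob = 1,
                         edge_score_range = c(0.905, 0.995),
                         n_lonely_annotated = 5L,
                         noise_edges = 0L,
                         noise_edge_score_range = c(0.4, 0.85),
                         noise_terms = 0L,
                         noise_term_size_range = c(6L, 30L),
                         bmd_windows = NULL,
                         lonely_bmd_window = c(40, 80),
                         trend_mix = c(inc = 0.46, dec = 0.47, bell = 0.03, U = 0.04),
                         with_ontology = TRUE,
                         parent_extra = 3L,
                         n_tf = 2L,
                         n_cotf = 1L) {
  if (sum(module_sizes) + n_lonely_annotated > n_deregulated) {
    abort_config("module sizes plus lonely annotated genes exceed the deregulated count")
  }
  if (n_deregulated > n_background) {
    abort_config("n_deregulated must not exceed n_background")
  }
  if (abs(sum(trend_mix) - 1) > 1e-8 ||
      !setequal(names(trend_mix), TREND_LEVELS)) {
    abort_config("trend_mix must be named probabilities over {inc, dec, bell, U} summing to 1")
  }
  if (intra_edge_prob < 0 || intra_edge_prob > 1) {
    abort_config("intra_edge_prob must lie in [0, 1]")
  }
  if (is.null(bmd_windows)) {
    bmd_windows <- lapply(seq_along(module_sizes), function(i) 4^(i - 1) * c(1, 2))
  }
  if (length(bmd_windows) != length(module_sizes)) {
    abort_config("need one bmd window per module")
  }
  structure(
    list(seed = as.integer(seed), n_background = as.integer(n_background),
         n_deregulated = as.integer(n_deregulated),
         module_sizes = as.integer(module_sizes),
         term_extra = as.integer(term_extra),
         intra_edge_prob = intra_edge_prob,
         edge_score_range = edge_score_range,
         n_lonely_annotated = as.integer(n_lonely_annotated),
         noise_edges = as.integer(noise_edges),
         noise_edge_score_range = noise_edge_score_range,
         noise_terms = as.integer(noise_terms),
         noise_term_size_range = as.integer(noise_term_size_range),
         bmd_windows = bmd_windows,
         lonely_bmd_window = lonely_bmd_window,
         trend_mix = trend_mix[TREND_LEVELS],
         with_ontology = isTRUE(with_ontology),
         parent_extra = as.integer(parent_extra),
         n_tf = as.integer(n_tf), n_cotf = as.integer(n_cotf)),
    class = "fixture_spec"
  )
}

#' Generate a synthetic input bundle on disk
#'
#' Writes `dr_results.csv`, `ppi_edges.tsv`, `planted.gmt`,
#' `regulators.tsv`, optionally `ontology_edges.tsv`, plus
#' `ground_truth.csv` (gene, planted module, planted term, expected fate
#' among clustered / fished / lonely) and a `manifest.csv`. The bundle is
#' a pure function of the spec: rerunning with the same spec rewrites
#' byte-identical files.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `manifest` and `ground_truth` tibbles.
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  genes <- sprintf("g%04d", seq_len(spec$n_background))
  drg <- sample(genes, spec$n_deregulated)
  n_mod <- length(spec$module_sizes)
  module_of <- stats::setNames(rep(NA_character_, length(drg)), drg)
  pos <- 1L
  modules <- list()
  for (i in seq_len(n_mod)) {
    m <- drg[pos:(pos + spec$module_sizes[i] - 1L)]
    modules[[paste0("M", i)]] <- m
    module_of[m] <- paste0("M", i)
    pos <- pos + spec$module_sizes[i]
  }
  lonely_annotated <- if (spec$n_lonely_annotated > 0) {
    drg[pos:(pos + spec$n_lonely_annotated - 1L)]
  } else character(0)
  pos <- pos + spec$n_lonely_annotated
  plain_lonely <- if (pos <= length(drg)) drg[pos:length(drg)] else character(0)
  bg_only <- setdiff(genes, drg)

  # --- PPI edges ---------------------------------------------------------
  edge_rows <- list()
  for (i in seq_len(n_mod)) {
    m <- modules[[i]]
    pairs <- utils::combn(m, 2)
    keep <- stats::runif(ncol(pairs)) <= spec$intra_edge_prob
    if (any(keep)) {
      edge_rows[[length(edge_rows) + 1L]] <- tibble::tibble(
        node_a = pairs[1, keep], node_b = pairs[2, keep],
        combined_score = stats::runif(sum(keep), spec$edge_score_range[1],
                                      spec$edge_score_range[2]))
    }
  }
  off_module <- c(lonely_annotated, plain_lonely)
  if (spec$noise_edges > 0 && length(off_module) >= 2) {
    na_ <- sample(off_module, spec$noise_edges, replace = TRUE)
    nb_ <- sample(off_module, spec$noise_edges, replace = TRUE)
    ok <- na_ != nb_
    edge_rows[[length(edge_rows) + 1L]] <- tibble::tibble(
      node_a = na_[ok], node_b = nb_[ok],
      combined_score = stats::runif(sum(ok), spec$noise_edge_score_range[1],
                                    spec$noise_edge_score_range[2]))
  }
  edges <- dplyr::bind_rows(edge_rows)
  edges$combined_score <- round(edges$combined_score, 4)

  # --- gene-set collection (GMT) ----------------------------------------
  gmt_lines <- character(0)
  ontology <- tibble::tibble(child = character(), parent = character())
  term_of_module <- character(n_mod)
  lonely_term <- stats::setNames(rep(NA_character_, length(lonely_annotated)),
                                 lonely_annotated)
  if (length(lonely_annotated) > 0) {
    lonely_term[] <- paste0("T_M", rep_len(seq_len(n_mod), length(lonely_annotated)))
  }
  for (i in seq_len(n_mod)) {
    tid <- paste0("T_M", i)
    term_of_module[i] <- tid
    extra <- sample(bg_only, spec$term_extra)
    tgenes <- sort_c(c(modules[[i]],
                       lonely_annotated[!is.na(lonely_term) & lonely_term == tid],
                       extra))
    gmt_lines <- c(gmt_lines, paste(c(tid, paste0("planted module ", i), tgenes),
                                    collapse = "\t"))
    if (spec$with_ontology) {
      pid <- paste0("T_P", i)
      pgenes <- sort_c(c(tgenes, sample(bg_only, spec$parent_extra)))
      gmt_lines <- c(gmt_lines, paste(c(pid, paste0("planted parent ", i), pgenes),
                                      collapse = "\t"))
      ontology <- dplyr::bind_rows(ontology,
                                   tibble::tibble(child = tid, parent = pid))
    }
  }
  if (spec$noise_terms > 0) {
    for (j in seq_len(spec$noise_terms)) {
      size <- sample(spec$noise_term_size_range[1]:spec$noise_term_size_range[2], 1)
      tgenes <- sort_c(sample(genes, size))
      gmt_lines <- c(gmt_lines, paste(c(sprintf("T_N%03d", j),
                                        sprintf("noise term %d", j), tgenes),
                                      collapse = "\t"))
    }
  }

  # --- dose-response results --------------------------------------------
  models <- c("Hill", "linear", "exponential", "Gauss-probit", "log-Gauss-probit")
  draw_bmd <- function(n, window) {
    round(exp(stats::runif(n, log(window[1]), log(window[2]))), 4)
  }
  tr_rows <- list()
  for (g in genes) {
    is_drg <- g %in% drg
    mod <- if (is_drg) module_of[[g]] else NA_character_
    n_tr <- if (is_drg && !is.na(mod) && (match(g, drg) %% 3 == 0)) 2L else 1L
    for (s in seq_len(n_tr)) {
      if (is_drg) {
        window <- if (!is.na(mod)) {
          spec$bmd_windows[[as.integer(sub("M", "", mod))]]
        } else {
          spec$lonely_bmd_window
        }
        bmd <- draw_bmd(1, window)
        trend <- sample(TREND_LEVELS, 1, prob = spec$trend_mix)
        tr_rows[[length(tr_rows) + 1L]] <- tibble::tibble(
          transcript_id = sprintf("t_%s_%d", g, s), gene_id = g,
          gene_name = paste0("name_", g), deregulated = TRUE,
          bmd = bmd, bmd_ci_low = round(bmd * 0.8, 4),
          bmd_ci_high = round(bmd * 1.3, 4), trend = trend,
          model = sample(models, 1))
      } else {
        tr_rows[[length(tr_rows) + 1L]] <- tibble::tibble(
          transcript_id = sprintf("t_%s_%d", g, s), gene_id = g,
          gene_name = paste0("name_", g), deregulated = FALSE,
          bmd = NA_real_, bmd_ci_low = NA_real_, bmd_ci_high = NA_real_,
          trend = NA_character_, model = NA_character_)
      }
    }
  }
  dr <- dplyr::bind_rows(tr_rows)

  # --- regulators --------------------------------------------------------
  reg_pool <- sample(drg, min(spec$n_tf + spec$n_cotf, length(drg)))
  regulators <- tibble::tibble(
    gene_id = reg_pool,
    class = c(rep("TF", min(spec$n_tf, length(reg_pool))),
              rep("CoTF", max(0, length(reg_pool) - spec$n_tf))))

  # --- ground truth ------------------------------------------------------
  truth <- tibble::tibble(
    gene_id = drg,
    module = ifelse(is.na(module_of[drg]), "", module_of[drg]),
    term_id = dplyr::case_when(
      !is.na(module_of[drg]) ~ paste0("T_", module_of[drg]),
      drg %in% lonely_annotated ~ unname(lonely_term[drg]),
      TRUE ~ ""),
    fate = dplyr::case_when(
      !is.na(module_of[drg]) ~ "clustered",
      drg %in% lonely_annotated ~ "fished",
      TRUE ~ "lonely"))
  truth <- dplyr::arrange(truth, gene_id)

  # --- write -------------------------------------------------------------
  files <- c(dr_results = "dr_results.csv", ppi_edges = "ppi_edges.tsv",
             gene_sets = "planted.gmt", regulators = "regulators.tsv",
             ground_truth = "ground_truth.csv")
  readr::write_csv(dr, file.path(out_dir, files["dr_results"]))
  readr::write_tsv(edges, file.path(out_dir, files["ppi_edges"]))
  writeLines(gmt_lines, file.path(out_dir, files["gene_sets"]))
  readr::write_tsv(regulators, file.path(out_dir, files["regulators"]))
  readr::write_csv(truth, file.path(out_dir, files["ground_truth"]))
  if (spec$with_ontology) {
    files <- c(files, ontology = "ontology_edges.tsv")
    readr::write_tsv(ontology, file.path(out_dir, "ontology_edges.tsv"))
  }
  manifest <- tibble::tibble(role = names(files), file = unname(files))
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(list(manifest = manifest, ground_truth = truth))
}

#' Load a generated fixture bundle as pipeline inputs
#'
#' @param dir Directory written by [generate_fixture()].
#' @param db_name Database name given to the bundled gene-set collection.
#' @return A list with `lists`, `edges`, `collections`, `ontology` (or
#'   `NULL`) and `ground_truth`, ready for [run_pipeline()].
#' @export
read_fixture <- function(dir, db_name = "PLANTED") {
  lists <- read_dr_results(file.path(dir, "dr_results.csv"))
  reg_path <- file.path(dir, "regulators.tsv")
  if (file.exists(reg_path)) lists <- annotate_regulators(lists, reg_path)
  edges <- read_ppi_edges(file.path(dir, "ppi_edges.tsv"))
  collections <- list(read_gmt(file.path(dir, "planted.gmt"), db_name,
                               lists$background))
  onto_path <- file.path(dir, "ontology_edges.tsv")
  ontology <- if (file.exists(onto_path)) read_ontology_edges(onto_path) else NULL
  truth <- readr::read_csv(file.path(dir, "ground_truth.csv"),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  list(lists = lists, edges = edges, collections = collections,
       ontology = ontology, ground_truth = truth)
}
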