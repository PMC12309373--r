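two_db_collections <- function(bg) {
  list(make_collection("DB1", list(F1 = bg[1:20], F2 = bg[11:30],
                                   fill1 = bg[31:90]), bg),
       make_collection("DB2", list(G1 = bg[1:15], fill2 = bg[16:60]), bg))
}

test_that("clusters sharing an enriched term merge by connected components", {
  bg <- sprintf("g%03d", 1:100)
  colls <- two_db_collections(bg)
  cl <- fishnet:::new_clustering(
    list(c1 = make_cluster("c1", bg[1:5], enr_rows("c1", "DB1", "F1")),
         c2 = make_cluster("c2", bg[6:10], enr_rows("c2", "DB1", c("F1", "F2"))),
         c3 = make_cluster("c3", bg[11:15], enr_rows("c3", "DB1", "F2"))),
    lonely = character(0))
  merged <- merge_clusters(cl, colls, pipeline_config())
  # chain c1-{F1}-c2-{F2}-c3 collapses into a single cluster
  expect_length(merged$clusters, 1)
  m <- merged$clusters[[1]]
  expect_equal(m$provenance, "merged")
  expect_setequal(m$merged_from, c("c1", "c2", "c3"))
  expect_setequal(m$genes, bg[1:15])
  expect_equal(m$cluster_id, "mc1")
  # idempotence: a second merge is a no-op
  again <- merge_clusters(merged, colls, pipeline_config())
  expect_identical(serialize(again, NULL), serialize(merged, NULL))
})

test_that("direct sharing merges only the sharing pair; disjoint terms are a no-op", {
  bg <- sprintf("g%03d", 1:100)
  colls <- two_db_collections(bg)
  cl <- fishnet:::new_clustering(
    list(c1 = make_cluster("c1", bg[1:5], enr_rows("c1", "DB1", "F1")),
         c2 = make_cluster("c2", bg[6:10], enr_rows("c2", "DB1", "F1")),
         c3 = make_cluster("c3", bg[11:15], enr_rows("c3", "DB1", "F2"))),
    lonely = character(0))
  merged <- merge_clusters(cl, colls, pipeline_config())
  expect_length(merged$clusters, 2)
  expect_true("mc1" %in% names(merged$clusters))
  expect_equal(merged$clusters$c3$provenance, "mcl")
  # no shared terms anywhere: clustering unchanged
  cl2 <- fishnet:::new_clustering(
    list(c1 = make_cluster("c1", bg[1:5], enr_rows("c1", "DB1", "F1")),
         c2 = make_cluster("c2", bg[6:10], enr_rows("c2", "DB2", "G1"))),
    lonely = character(0))
  merged2 <- merge_clusters(cl2, colls, pipeline_config())
  expect_setequal(names(merged2$clusters), c("c1", "c2"))
  expect_true(all(vapply(merged2$clusters, `[[`, character(1), "provenance") == "mcl"))
})

test_that("term sharing is scoped to a database: same id in two databases never merges", {
  bg <- sprintf("g%03d", 1:100)
  colls <- two_db_collections(bg)
  cl <- fishnet:::new_clustering(
    list(c1 = make_cluster("c1", bg[1:5], enr_rows("c1", "DB1", "SHARED")),
         c2 = make_cluster("c2", bg[6:10], enr_rows("c2", "DB2", "SHARED"))),
    lonely = character(0))
  merged <- merge_clusters(cl, colls, pipeline_config())
  expect_length(merged$clusters, 2)
})

test_that("lonely genes are fished into every cluster enriching one of their annotations", {
  bg <- sprintf("g%03d", 1:100)
  # gene g050 annotated to F1 (DB1) and G1 (DB2); g051 annotated nowhere useful
  colls <- list(
    make_collection("DB1", list(F1 = c(bg[1:8], "g050"),
                                F3 = bg[20:30], fill = bg[31:90]), bg),
    make_collection("DB2", list(G1 = c(bg[9:15], "g050")), bg))
  cl <- fishnet:::new_clustering(
    list(c1 = make_cluster("c1", bg[1:5], enr_rows("c1", "DB1", "F1")),
         c2 = make_cluster("c2", bg[9:12], enr_rows("c2", "DB2", "G1"))),
    lonely = c("g050", "g051"))
  out <- fish_lonely(cl, colls, pipeline_config())
  expect_equal(out$fishing$gene_id, "g050")
  expect_equal(out$fishing$friendliness, 2L)
  expect_setequal(out$fishing$joined_clusters[[1]], c("c1", "c2"))
  expect_true("g050" %in% out$clustering$clusters$c1$genes)
  expect_true("g050" %in% out$clustering$clusters$c2$genes)
  expect_equal(out$clustering$clusters$c1$provenance, "expanded")
  expect_equal(out$clustering$lonely, "g051")
  # friendliness = number of joined clusters; via terms non-empty
  expect_equal(lengths(out$fishing$joined_clusters), out$fishing$friendliness)
  expect_true(all(lengths(out$fishing$via_terms[[1]]) > 0))
})

test_that("fishing only matches terms retained as enriched, never mere annotations", {
  bg <- sprintf("g%03d", 1:100)
  colls <- list(make_collection("DB1",
                                list(F1 = bg[1:8],
                                     F_unretained = c(bg[40:50], "g050"),
                                     T_small = c(bg[1:3], "g051")), bg))
  cl <- fishnet:::new_clustering(
    list(c1 = make_cluster("c1", bg[1:5], enr_rows("c1", "DB1", "F1"))),
    lonely = c("g050", "g051"))
  out <- fish_lonely(cl, colls, pipeline_config())
  # g050's term is not enriched in any cluster; g051's term is under the
  # size window (never eligible): both stay lonely
  expect_equal(nrow(out$fishing), 0)
  expect_setequal(out$clustering$lonely, c("g050", "g051"))
  # fishing never shrinks a cluster
  expect_true(all(bg[1:5] %in% out$clustering$clusters$c1$genes))
})

test_that("the full pipeline recovers planted modules on a noiseless fixture", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(seed = 7)
  generate_fixture(spec, dir)
  inp <- read_fixture(dir)
  cfg <- pipeline_config(seed = 7)
  res <- run_pipeline(inp$lists, inp$edges, inp$collections, cfg,
                      ontology = inp$ontology)
  truth <- inp$ground_truth

  # three clusters, gene sets equal to the planted modules plus fished genes
  expect_length(res$clustering$clusters, 3)
  planted_sets <- split(truth$gene_id[truth$fate == "clustered"],
                        truth$module[truth$fate == "clustered"])
  core_sets <- lapply(res$clustering$clusters,
                      function(cl) sort(setdiff(cl$genes, cl$fished)))
  expect_true(setequal(unname(core_sets), unname(lapply(planted_sets, sort))))

  # each cluster enriches exactly its planted term (driver-filtered)
  for (cl in res$clustering$clusters) {
    expect_equal(nrow(cl$enriched), 1)
    module <- unique(truth$module[truth$gene_id %in% setdiff(cl$genes, cl$fished)])
    expect_equal(cl$enriched$term_id, paste0("T_", module))
    expect_lte(cl$enriched$q_fdr, 0.05)
  }
  # no merges on distinct planted terms
  expect_true(all(vapply(res$clustering$clusters, `[[`, character(1),
                         "provenance") %in% c("mcl", "expanded")))
  # all planted-lonely genes fished, each into its annotated module's cluster
  fishable <- truth$gene_id[truth$fate == "fished"]
  expect_setequal(res$fishing$gene_id, fishable)
  expect_true(all(res$fishing$friendliness >= 1))
  # conservation with overlap: clusters plus lonely cover the deregulated set
  covered <- union(unlist(lapply(res$clustering$clusters, `[[`, "genes")),
                   res$clustering$lonely)
  expect_setequal(covered, inp$lists$deregulated)
})

test_that("two planted cliques annotated to one shared term merge into one cluster", {
  dir <- withr::local_tempdir()
  generate_fixture(fixture_spec(seed = 5, with_ontology = FALSE), dir)
  inp <- read_fixture(dir)
  # rewrite the collection so modules 1 and 2 share a single planted term
  truth <- inp$ground_truth
  m1 <- truth$gene_id[truth$module %in% "M1"]
  m2 <- truth$gene_id[truth$module %in% "M2"]
  m3 <- truth$gene_id[truth$module %in% "M3"]
  bg <- inp$lists$background
  coll <- make_collection("PLANTED",
                          list(T_shared = c(m1, m2), T_M3 = c(m3, bg[1:2])),
                          bg)
  res <- run_pipeline(inp$lists, inp$edges, list(coll),
                      pipeline_config(seed = 5))
  prov <- vapply(res$clustering$clusters, `[[`, character(1), "provenance")
  expect_equal(sum(prov %in% c("merged", "expanded") &
                     vapply(res$clustering$clusters,
                            function(cl) length(cl$merged_from) > 0, logical(1))), 1)
  merged <- res$clustering$clusters[[which(vapply(res$clustering$clusters,
                                                  function(cl) length(cl$merged_from) > 0,
                                                  logical(1)))]]
  expect_setequal(setdiff(merged$genes, merged$fished), c(m1, m2))
})

test_that("an empty deregulated list short-circuits the pipeline", {
  bg <- sprintf("g%03d", 1:50)
  lists <- make_lists(bg, character(0))
  colls <- list(make_collection("DB1", list(F1 = bg[1:10]), bg))
  edges <- tibble::tibble(node_a = "g001", node_b = "g002", score = 0.95)
  res <- run_pipeline(lists, edges, colls, pipeline_config())
  expect_length(res$clustering$clusters, 0)
  expect_equal(nrow(res$enrichments), 0)
  expect_true(any(grepl("short-circuit", res$log)))
})

test_that("standard whole-list ORA shares the filters and degenerates correctly", {
  s_bg <- sprintf("g%03d", 1:200)
  planted <- s_bg[1:8]
  fillers <- split(s_bg, rep(1:10, length.out = 200))
  names(fillers) <- sprintf("F%02d", 1:10)
  coll <- make_collection("DB", c(list(T_planted = planted), fillers), s_bg)
  # a planted 8-gene term against a 100-gene deregulated query is retained
  lists <- make_lists(s_bg, s_bg[1:100])
  res <- run_standard(lists, list(coll), pipeline_config())
  expect_true("T_planted" %in% res$term_id)
  expect_true(all(res$query_id == "standard"))
  row <- res[res$term_id == "T_planted", ]
  p_oracle <- hyper_tail_oracle(8, 100, 8, 200)
  expect_equal(row$p_raw, p_oracle, tolerance = 1e-12)
  # deregulated = background: every overlap is forced, nothing is enriched
  lists_all <- make_lists(s_bg, s_bg)
  res_all <- run_standard(lists_all, list(coll), pipeline_config())
  expect_equal(nrow(res_all), 0)
})

test_that("workflow comparison sets obey the deregulated-list bound", {
  dir <- withr::local_tempdir()
  generate_fixture(fixture_spec(seed = 3), dir)
  inp <- read_fixture(dir)
  res <- run_pipeline(inp$lists, inp$edges, inp$collections,
                      pipeline_config(seed = 3), ontology = inp$ontology)
  cmp <- compare_workflows(res, inp$lists)
  expect_lte(cmp$n_standard + cmp$n_anchored_only, cmp$n_deregulated)
  expect_equal(cmp$n_shared + cmp$n_standard_only, cmp$n_standard)
  expect_equal(cmp$n_shared + cmp$n_anchored_only, cmp$n_anchored)
  expect_equal(cmp$n_neither,
               cmp$n_deregulated - cmp$n_shared - cmp$n_standard_only -
                 cmp$n_anchored_only)
})
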