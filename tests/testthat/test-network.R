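test_that("graph construction thresholds on confidence and restricts to deregulated genes", {
  lists <- make_lists(c("a", "b", "c", "x"), c("a", "b", "c"))
  edges <- tibble::tibble(node_a = c("a", "b", "a"),
                          node_b = c("b", "c", "x"),
                          score = c(0.95, 0.45, 0.99))
  g <- build_graph(lists, edges, pipeline_config(confidence_min = 0.9))
  expect_setequal(g$nodes, c("a", "b"))
  expect_equal(nrow(g$edges), 1)
  # STRING's own default threshold keeps the weaker edge
  g2 <- build_graph(lists, edges, pipeline_config(confidence_min = 0.4))
  expect_setequal(g2$nodes, c("a", "b", "c"))
  expect_equal(nrow(g2$edges), 2)
  # raising the threshold never adds an edge (monotone thresholding)
  for (thr in seq(0, 1, by = 0.1)) {
    lo <- build_graph(lists, edges, pipeline_config(confidence_min = thr))
    hi <- build_graph(lists, edges,
                      pipeline_config(confidence_min = min(1, thr + 0.1)))
    expect_true(all(paste(hi$edges$node_a, hi$edges$node_b) %in%
                      paste(lo$edges$node_a, lo$edges$node_b)))
  }
})

test_that("MCL recovers disconnected cliques exactly", {
  e <- dplyr::bind_rows(clique_edges(c("a", "b", "c"), 0.95),
                        clique_edges(c("d", "e", "f"), 0.92))
  part <- mcl_cluster(make_graph(e), pipeline_config(inflation = 4))
  expect_length(part, 2)
  expect_true(setequal(unname(lapply(part, sort)),
                       list(c("a", "b", "c"), c("d", "e", "f"))))
  # agrees with the connected-components oracle
  expect_true(setequal(unname(lapply(part, sort)), components_oracle(e)))
})

test_that("MCL partition covers every node exactly once and is label-invariant", {
  set.seed(11)
  for (rep in 1:5) {
    sizes <- sample(3:8, 3)
    nodes <- sprintf("n%02d", seq_len(sum(sizes)))
    sets <- split(nodes, rep(seq_along(sizes), sizes))
    e <- dplyr::bind_rows(lapply(sets, clique_edges, score = 0.95))
    part <- mcl_cluster(make_graph(e), pipeline_config())
    expect_setequal(unlist(part), nodes)
    expect_equal(sum(lengths(part)), length(nodes))
    # relabeled copy gives the same partition up to relabeling
    relab <- setNames(sprintf("z%02d", seq_along(nodes)), nodes)
    e2 <- tibble::tibble(node_a = unname(relab[e$node_a]),
                         node_b = unname(relab[e$node_b]), score = e$score)
    part2 <- mcl_cluster(make_graph(e2), pipeline_config())
    remapped <- lapply(part, function(cl) sort(unname(relab[cl])))
    expect_true(setequal(unname(lapply(part2, sort)), unname(remapped)))
  }
})

test_that("MCL handles degenerate graphs", {
  empty <- make_graph(tibble::tibble(node_a = character(),
                                     node_b = character(), score = numeric()))
  expect_length(mcl_cluster(empty, pipeline_config()), 0)
  # a single isolated node (self-loop only) forms a singleton cluster
  single <- structure(list(nodes = "a",
                           edges = tibble::tibble(node_a = character(),
                                                  node_b = character(),
                                                  score = numeric()),
                           confidence_min = 0.9), class = "ppi_graph")
  part <- mcl_cluster(single, pipeline_config())
  expect_equal(part, list(`1` = "a"), ignore_attr = TRUE)
  # non-convergence surfaces as a typed error, not a partial result
  # (an asymmetric path needs more than one iteration to stabilise)
  e <- tibble::tibble(node_a = c("a", "b"), node_b = c("b", "c"),
                      score = c(0.95, 0.92))
  expect_error(mcl_cluster(make_graph(e), pipeline_config(mcl_max_iter = 1)),
               "converge", class = "fishnet_convergence_error")
})

test_that("size filter retains >= min_cluster_size and conserves genes", {
  lists <- make_lists(sprintf("g%02d", 1:10), sprintf("g%02d", 1:8))
  partition <- list(c("g01", "g02", "g03", "g04"), c("g05", "g06", "g07"))
  # g08 is deregulated but absent from the graph
  cl <- partition_and_filter(lists, partition, pipeline_config(min_cluster_size = 4))
  expect_length(cl$clusters, 1)
  expect_setequal(cl$clusters$c1$genes, c("g01", "g02", "g03", "g04"))
  expect_setequal(cl$lonely, c("g05", "g06", "g07", "g08"))
  # conservation: |lonely| + sum of cluster sizes = |deregulated|
  expect_equal(length(cl$lonely) +
                 sum(vapply(cl$clusters, function(x) length(x$genes), integer(1))),
               length(lists$deregulated))
  # min size 1 keeps every cell; lonely is only the off-graph gene
  cl1 <- partition_and_filter(lists, partition, pipeline_config(min_cluster_size = 1))
  expect_length(cl1$clusters, 2)
  expect_equal(cl1$lonely, "g08")
  # empty partition: everything lonely
  cl0 <- partition_and_filter(lists, list(), pipeline_config())
  expect_length(cl0$clusters, 0)
  expect_setequal(cl0$lonely, lists$deregulated)
})

test_that("cluster ids are assigned by decreasing size with lexicographic ties", {
  lists <- make_lists(letters[1:12], letters[1:12])
  partition <- list(c("e", "f", "g", "h"), c("a", "b", "c", "d"),
                    c("i", "j", "k", "l"))
  cl <- partition_and_filter(lists, partition, pipeline_config())
  # equal sizes: ties broken by smallest member gene id
  expect_equal(cl$clusters$c1$genes[1], "a")
  expect_equal(cl$clusters$c2$genes[1], "e")
  expect_equal(cl$clusters$c3$genes[1], "i")
})

test_that("clustering runs are deterministic", {
  set.seed(3)
  sizes <- c(5, 4, 6)
  sets <- split(sprintf("n%02d", 1:15), rep(1:3, sizes))
  e <- dplyr::bind_rows(lapply(sets, function(s) clique_edges(s, runif(1, .9, 1))))
  lists <- make_lists(sprintf("n%02d", 1:15), sprintf("n%02d", 1:15))
  run <- function() {
    g <- build_graph(lists, e, pipeline_config())
    partition_and_filter(lists, mcl_cluster(g, pipeline_config()),
                         pipeline_config())
  }
  expect_identical(serialize(run(), NULL), serialize(run(), NULL))
})
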