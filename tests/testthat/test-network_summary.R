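toy_net <- function() {
  as_network(data.frame(
    source = c("a", "a", "b", "c", "d"),
    target = c("b", "c", "c", "d", "e"),
    condition = c("c1", "c1", "c1", "c2", "c2"),
    similarity = c(0.9, 0.8, 0.7, 0.6, -0.6)))
}

test_that("condition subnetworks partition labeled edges", {
  net <- toy_net()
  s1 <- extract_condition_subnetwork(net, "c1")
  s2 <- extract_condition_subnetwork(net, "c2")
  expect_equal(nrow(s1$edges), 3)
  expect_setequal(s2$nodes, c("c", "d", "e"))
  # an edge labeled only c1 is absent from c2
  expect_false("a\rb" %in% paste(s2$edges$gene_a, s2$edges$gene_b, sep = "\r"))
  # union of subnetwork edges = full edge set
  all_keys <- sort(unique(c(paste(s1$edges$gene_a, s1$edges$gene_b),
                            paste(s2$edges$gene_a, s2$edges$gene_b))))
  expect_equal(all_keys, sort(paste(net$edges$gene_a, net$edges$gene_b)))
  expect_error(extract_condition_subnetwork(net, "c9"), "unknown condition")
})

test_that("unique elements agree with a brute-force set difference", {
  net <- toy_net()
  s1 <- extract_condition_subnetwork(net, "c1")
  s2 <- extract_condition_subnetwork(net, "c2")
  u1 <- unique_elements(s1, list(s2))
  expect_setequal(u1$nodes, c("a", "b"))          # c is shared
  expect_equal(nrow(u1$edges), 3)                  # no c1 edge occurs in c2

  # random partitions vs brute force
  set.seed(44)
  for (i in 1:10) {
    n <- 12
    ed <- data.frame(source = sprintf("n%02d", sample(n, 20, TRUE)),
                     target = sprintf("n%02d", sample(n, 20, TRUE)),
                     condition = sample(c("x", "y", "z"), 20, TRUE))
    ed <- ed[ed$source != ed$target, ]
    net <- as_network(ed)
    subs <- lapply(names(net$conditions), extract_condition_subnetwork, net = net)
    names(subs) <- names(net$conditions)
    for (co in names(subs)) {
      others <- subs[setdiff(names(subs), co)]
      u <- unique_elements(subs[[co]], others)
      brute_nodes <- setdiff(subs[[co]]$nodes,
                             unlist(lapply(others, function(s) s$nodes)))
      expect_setequal(u$nodes, brute_nodes)
      key <- function(s) paste(s$edges$gene_a, s$edges$gene_b)
      brute_edges <- setdiff(key(subs[[co]]), unlist(lapply(others, key)))
      expect_setequal(paste(u$edges$gene_a, u$edges$gene_b), brute_edges)
    }
  }
})

test_that("summary statistics match their definitions on canonical graphs", {
  triangle <- as_network(data.frame(source = c("a", "b", "c"),
                                    target = c("b", "c", "a")))
  s <- summarize_network(triangle)
  expect_equal(s$avg_clustering_coefficient, 1)
  expect_equal(s$avg_connectivity, 2)

  star <- as_network(data.frame(source = "hub", target = paste0("leaf", 1:5)))
  expect_equal(summarize_network(star)$avg_clustering_coefficient, 0)

  # a tree is acyclic: <C> = 0 (degree-<2 nodes contribute 0, not NA)
  tree <- as_network(data.frame(source = sprintf("n%02d", 1:35),
                                target = sprintf("n%02d", c(36, 1:34))))
  st <- summarize_network(tree)
  expect_equal(st$n_nodes, 36)
  expect_equal(st$n_edges, 35)
  expect_equal(st$avg_clustering_coefficient, 0)
})

test_that("local clustering agrees with brute-force triangle counting", {
  for (seed in c(7, 13, 29)) {
    net <- random_graph_net(n_nodes = 30, n_edges = 60, seed = seed)
    s <- summarize_network(net)
    brute <- brute_local_clustering(net$edges[, c("gene_a", "gene_b")],
                                    net$nodes)
    expect_equal(s$avg_clustering_coefficient, mean(brute), tolerance = 1e-12)
    expect_equal(s$avg_connectivity, 2 * s$n_edges / s$n_nodes)
  }
})

test_that("published-count arithmetic reproduces all derived cells", {
  der <- derive_attribute_cells()
  expect_equal(der$connectivity, c(14.85, 15.71, 2.59, 2.41, 2.42))
  expect_equal(der$unique_connectivity, c(NA, 15.63, 1.17, 2.26, 2.40))
  expect_equal(der$unique_node_pct, c(NA, 97.93, 3.40, 97.79, 98.95))
  expect_equal(der$unique_edge_pct, c(NA, 97.38, 1.53, 92.02, 97.98))
})

test_that("network export/import round-trips in both formats", {
  net <- toy_net()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, p1, "tsv_edgelist")
  r1 <- import_network(p1, "tsv_edgelist")
  expect_setequal(paste(r1$edges$gene_a, r1$edges$gene_b),
                  paste(net$edges$gene_a, net$edges$gene_b))
  expect_equal(sort(r1$edges$similarity), sort(net$edges$similarity))

  p2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, p2, "graphml")
  expect_true(any(grepl("graphml", readLines(p2, n = 5))))
  r2 <- import_network(p2, "graphml")
  expect_setequal(r2$nodes, net$nodes)
  expect_equal(nrow(r2$edges), nrow(net$edges))

  empty <- as_network(data.frame(source = character(), target = character()))
  p3 <- withr::local_tempfile(fileext = ".tsv")
  export_network(empty, p3, "tsv_edgelist")
  expect_equal(length(readLines(p3)), 1L)  # header only
})
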