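test_that("GRN loading validates columns and collapses duplicates", {
  d <- withr::local_tempdir()
  p <- file.path(d, "grn.tsv")
  writeLines(c("tf\ttarget", "T1\tA", "T1\tB", "T2\tA"), p)
  g <- load_grn(p)
  expect_equal(nrow(g), 3)

  writeLines(c("tf\ttarget", "T1\tA", "T1\tA", "T2\tA"), p)
  expect_message(g2 <- load_grn(p), "1 duplicate")
  expect_equal(nrow(g2), 2)

  writeLines(c("from\tto", "T1\tA"), p)
  expect_error(load_grn(p), "tf")

  # round trip preserves the edge set
  write.table(g, file.path(d, "out.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  g3 <- load_grn(file.path(d, "out.tsv"))
  expect_equal(g3$tf, g$tf)
  expect_equal(g3$target, g$target)
})

test_that("targeting-edge selection keeps exactly edges into the subnetwork", {
  net <- as_network(data.frame(source = c("A", "C"), target = c("B", "D"),
                               condition = "c1"))
  grn <- as_grn(data.frame(tf = c("T1", "T1", "T2"),
                           target = c("A", "Z", "D")))
  sel <- select_targeting_edges(grn, net)
  expect_equal(nrow(sel), 2)
  expect_false("Z" %in% sel$target)
  # all targets inside: identity
  grn2 <- as_grn(data.frame(tf = "T1", target = c("A", "B")))
  expect_equal(nrow(select_targeting_edges(grn2, net)), 2)

  set.seed(50)
  for (i in 1:10) {
    nodes <- sprintf("n%02d", 1:15)
    grn_r <- as_grn(unique(data.frame(tf = sample(nodes, 30, TRUE),
                                      target = sample(nodes, 30, TRUE))))
    sub <- random_graph_net(10, 12, seed = i)
    sel <- select_targeting_edges(grn_r, sub)
    expect_setequal(paste(sel$tf, sel$target),
                    paste(grn_r$tf, grn_r$target)[grn_r$target %in% sub$nodes])
  }
})

test_that("triangle extraction equals brute-force triple enumeration", {
  net <- as_network(data.frame(source = "A", target = "B", condition = "c1"))
  grn <- as_grn(data.frame(tf = c("T", "T"), target = c("A", "B")))
  tri <- extract_triangles(grn, net)
  expect_equal(nrow(tri), 1)
  expect_equal(tri$tf, "T")

  grn_half <- as_grn(data.frame(tf = "T", target = "A"))
  expect_equal(nrow(extract_triangles(grn_half, net)), 0)

  set.seed(55)
  for (i in 1:15) {
    nodes <- sprintf("n%02d", seq_len(sample(10:30, 1)))
    sub <- random_graph_net(length(nodes), sample(10:40, 1), seed = i * 3)
    grn_r <- as_grn(unique(data.frame(
      tf = sample(sprintf("t%02d", 1:8), 40, TRUE),
      target = sample(nodes, 40, TRUE))))
    tri <- extract_triangles(grn_r, sub)
    brute <- brute_triangles(grn_r, sub)
    expect_equal(nrow(tri), nrow(brute))
    if (nrow(tri))
      expect_equal(paste(tri$tf, tri$gene_a, tri$gene_b),
                   paste(brute$tf, brute$gene_a, brute$gene_b))
    # referential integrity: all three edges exist in their sources
    for (j in seq_len(nrow(tri))) {
      expect_true(any(grn_r$tf == tri$tf[j] & grn_r$target == tri$gene_a[j]))
      expect_true(any(grn_r$tf == tri$tf[j] & grn_r$target == tri$gene_b[j]))
      expect_true(any(sub$edges$gene_a == tri$gene_a[j] &
                        sub$edges$gene_b == tri$gene_b[j]))
    }
    # invariance to input row order
    perm <- sample(nrow(grn_r))
    tri_p <- extract_triangles(as_grn(grn_r[perm, ]), sub)
    expect_equal(tri_p[, 1:3], tri[, 1:3])
  }
})

test_that("triangle significance annotation reflects the assessments", {
  net <- as_network(data.frame(source = c("A", "C"), target = c("B", "D"),
                               condition = "c1", similarity = c(0.9, 0.8)))
  grn <- as_grn(data.frame(tf = c("T", "T", "U", "U"),
                           target = c("A", "B", "C", "D")))
  asm <- data.frame(tf = c("T", "T", "U", "U"), tr = c("A", "B", "C", "D"),
                    ratio_significant = TRUE,
                    doubly_significant = c(TRUE, TRUE, TRUE, FALSE))
  tri <- extract_triangles(grn, net, asm)
  expect_equal(tri$fully_significant, c(TRUE, FALSE))
})

test_that("the merged export graph carries node and edge annotations", {
  net <- as_network(data.frame(source = "A", target = "B", condition = "c1"))
  grn <- as_grn(data.frame(tf = c("T", "T"), target = c("A", "B")))
  de <- data.frame(gene = c("A", "B", "T"), direction = c("up", "down", "down"))
  asm <- data.frame(tf = c("T", "T"), tr = c("A", "B"),
                    ratio_significant = c(TRUE, FALSE))
  g <- merge_for_export(net, grn, de = de, assessments = asm)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
  expect_equal(sum(igraph::E(g)$edge_type == "regulatory"), 2)
  expect_equal(sum(igraph::E(g)$edge_type == "coexpression"), 1)
  v <- igraph::as_data_frame(g, "vertices")
  expect_true(v$is_tf[v$name == "T"])
  expect_equal(v$de_direction[v$name == "A"], "up")
  # graphml round trip
  p <- withr::local_tempfile(fileext = ".graphml")
  igraph::write_graph(g, p, format = "graphml")
  g2 <- igraph::read_graph(p, format = "graphml")
  expect_equal(igraph::ecount(g2), 3)
  expect_setequal(igraph::V(g2)$name, c("A", "B", "T"))
})
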