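# fixtures and independent oracles shared across test files

make_gem <- function(values, scale = "log2", genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%03d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  gem(values, scale)
}

two_cond_annot <- function(n_a, n_b, labels = c("a", "b")) {
  data.frame(sample = sprintf("s%03d", seq_len(n_a + n_b)),
             condition = rep(labels, c(n_a, n_b)),
             stringsAsFactors = FALSE)
}

# brute-force local clustering coefficient (adjacency triple counting)
brute_local_clustering <- function(edges_df, nodes) {
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges_df))) {
    A[edges_df[[1]][i], edges_df[[2]][i]] <- 1
    A[edges_df[[2]][i], edges_df[[1]][i]] <- 1
  }
  vapply(nodes, function(v) {
    nb <- nodes[A[v, ] == 1]
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, 0)
}

# brute-force triangle enumeration: all (tf, a, b) triples
brute_triangles <- function(grn, subnet) {
  ed <- subnet$edges
  out <- list()
  for (i in seq_len(nrow(ed))) {
    a <- ed$gene_a[i]; b <- ed$gene_b[i]
    for (tf in unique(grn$tf)) {
      has_a <- any(grn$tf == tf & grn$target == a)
      has_b <- any(grn$tf == tf & grn$target == b)
      if (has_a && has_b)
        out[[length(out) + 1L]] <- c(tf = tf, gene_a = a, gene_b = b)
    }
  }
  if (!length(out)) return(data.frame(tf = character(), gene_a = character(),
                                      gene_b = character()))
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  df[order(df$tf, df$gene_a, df$gene_b), , drop = FALSE]
}

# mixture log-likelihood computed from scratch (own bivariate normal
# density), for the BIC selection oracle
mixture_loglik <- function(dat, pro, mean, sigma) {
  k <- length(pro)
  dens <- sapply(seq_len(k), function(j) {
    mu <- mean[, j]; S <- sigma[, , j]
    Sinv <- solve(S)
    dv <- sweep(dat, 2, mu)
    q <- rowSums((dv %*% Sinv) * dv)
    exp(-q / 2) / (2 * pi * sqrt(det(S)))
  })
  if (k == 1) dens <- matrix(dens, ncol = 1)
  sum(log(dens %*% pro))
}

# two well-separated sample classes (columns), log2 scale
separable_gem <- function(n_per = 100, n_genes = 20, delta = 5, seed = 71) {
  set.seed(seed)
  lat <- cbind(matrix(rnorm(n_genes * n_per, 5, 1), n_genes),
               matrix(rnorm(n_genes * n_per, 5 + delta, 1), n_genes))
  make_gem(lat, "log2", genes = sprintf("G%03d", seq_len(n_genes)),
           samples = sprintf("s%03d", seq_len(2 * n_per)))
}

random_graph_net <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  as_network(data.frame(source = pairs[pick, 1], target = pairs[pick, 2],
                        condition = "c1", stringsAsFactors = FALSE))
}
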