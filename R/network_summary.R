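#' Build an undirected network from a ranked edge table
#'
#' Edges are unordered gene pairs, deduplicated; an edge may carry several
#' condition labels (one input row each), giving the condition partition
#' used for subnetwork extraction.
#'
#' @param edges `csgcn_edges` data frame (or anything with `source`,
#'   `target` and optionally `condition` columns).
#' @return object of class `"csgcn_network"`: list with `nodes`
#'   (character), `edges` (data frame `gene_a < gene_b` plus attributes,
#'   unique pairs), and `conditions` (condition -> edge-key character
#'   vector).
#' @export
as_network <- function(edges) {
  stopifnot(all(c("source", "target") %in% names(edges)))
  if (!nrow(edges)) {
    return(structure(list(nodes = character(),
                          edges = edges[0, , drop = FALSE],
                          conditions = list()),
                     class = "csgcn_network"))
  }
  a <- pmin(edges$source, edges$target)
  b <- pmax(edges$source, edges$target)
  if (any(a == b)) stop("self-loop in edge table")
  key <- paste(a, b, sep = "\r")
  ed <- edges
  ed$gene_a <- a; ed$gene_b <- b
  conditions <- list()
  if ("condition" %in% names(edges)) {
    for (co in sort(unique(edges$condition)))
      conditions[[co]] <- unique(key[edges$condition == co])
  }
  uniq <- !duplicated(key)
  structure(list(nodes = sort(unique(c(a, b))),
                 edges = ed[uniq, , drop = FALSE],
                 conditions = conditions),
            class = "csgcn_network")
}

#' @export
print.csgcn_network <- function(x, ...) {
  cat(sprintf("csGCN network: %d nodes, %d edges, %d condition label(s)\n",
              length(x$nodes), nrow(x$edges), length(x$conditions)))
  invisible(x)
}

edge_keys <- function(net) paste(net$edges$gene_a, net$edges$gene_b, sep = "\r")

#' Extract the subnetwork of one condition
#'
#' @param net a `csgcn_network`.
#' @param condition condition label present in the network's partition.
#' @return a `csgcn_network` restricted to edges labeled `condition`;
#'   nodes are the endpoints of those edges.
#' @export
extract_condition_subnetwork <- function(net, condition) {
  stopifnot(inherits(net, "csgcn_network"))
  if (!condition %in% names(net$conditions))
    stop("unknown condition: ", condition)
  keep <- edge_keys(net) %in% net$conditions[[condition]]
  ed <- net$edges[keep, , drop = FALSE]
  structure(list(nodes = sort(unique(c(ed$gene_a, ed$gene_b))),
                 edges = ed,
                 conditions = stats::setNames(
                   list(net$conditions[[condition]]), condition)),
            class = "csgcn_network")
}

#' Nodes and edges unique to one subnetwork
#'
#' @param sub a condition subnetwork.
#' @param others list of the other condition subnetworks.
#' @return list `(nodes, edges)`: elements of `sub` appearing in no other
#'   subnetwork (edges as a two-column data frame).
#' @export
unique_elements <- function(sub, others) {
  other_nodes <- unique(unlist(lapply(others, function(n) n$nodes)))
  other_keys <- unique(unlist(lapply(others, edge_keys)))
  un <- setdiff(sub$nodes, other_nodes)
  ue <- sub$edges[!(edge_keys(sub) %in% other_keys),
                  c("gene_a", "gene_b"), drop = FALSE]
  rownames(ue) <- NULL
  list(nodes = un, edges = ue)
}

#' Average connectivity (mean degree) from counts
#'
#' @param n_nodes,n_edges node and edge counts.
#' @return 2E/N (unrounded; see [round_half_up] for display).
#' @export
avg_connectivity <- function(n_nodes, n_edges) {
  ifelse(n_nodes == 0, 0, 2 * n_edges / n_nodes)
}

#' Round half away from zero (display convention)
#'
#' @param x numeric; @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Global attributes of a network
#'
#' Mean degree 2E/N and the average local clustering coefficient, where a
#' node of degree < 2 contributes 0 (so an acyclic network has <C> = 0).
#' When `others` is supplied, unique node/edge counts and percentages
#' (relative to this network's own totals) are included.
#'
#' @param net a `csgcn_network`.
#' @param others optional list of sibling subnetworks for uniqueness.
#' @return one-row data frame: `n_nodes`, `n_edges`, `avg_connectivity`,
#'   `avg_clustering_coefficient`, and with `others`: `unique_nodes`,
#'   `unique_edges`, `unique_connectivity`, `unique_node_pct`,
#'   `unique_edge_pct`.
#' @export
summarize_network <- function(net, others = NULL) {
  stopifnot(inherits(net, "csgcn_network"))
  n <- length(net$nodes); e <- nrow(net$edges)
  if (n == 0) {
    warning("empty network")
    cc <- 0
  } else {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("gene_a", "gene_b"), drop = FALSE],
      directed = FALSE, vertices = net$nodes)
    lc <- igraph::transitivity(g, type = "local", isolates = "zero")
    lc[is.na(lc)] <- 0
    cc <- mean(lc)
  }
  out <- data.frame(n_nodes = n, n_edges = e,
                    avg_connectivity = avg_connectivity(n, e),
                    avg_clustering_coefficient = cc)
  if (!is.null(others)) {
    u <- unique_elements(net, others)
    out$unique_nodes <- length(u$nodes)
    out$unique_edges <- nrow(u$edges)
    out$unique_connectivity <- avg_connectivity(length(u$nodes), nrow(u$edges))
    out$unique_node_pct <- if (n) 100 * length(u$nodes) / n else 0
    out$unique_edge_pct <- if (e) 100 * nrow(u$edges) / e else 0
  }
  out
}

#' Attribute table for a network and all its condition subnetworks
#'
#' @param net the full `csgcn_network`.
#' @return data frame with one row for the full network and one per
#'   condition, mirroring the usual published global-attribute table.
#' @export
network_attribute_table <- function(net) {
  conds <- names(net$conditions)
  subs <- lapply(conds, extract_condition_subnetwork, net = net)
  names(subs) <- conds
  rows <- list(cbind(data.frame(network = "full"), summarize_network(net)))
  for (co in conds) {
    others <- subs[setdiff(conds, co)]
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(network = co), summarize_network(subs[[co]], others))
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    for (cl in c("unique_nodes", "unique_edges", "unique_connectivity",
                 "unique_node_pct", "unique_edge_pct"))
      if (is.null(r[[cl]])) r[[cl]] <- NA
    r
  }))
  rownames(out) <- NULL
  out
}

#' Export / import a network
#'
#' `tsv_edgelist` writes the attribute-bearing edge table;
#' `graphml` goes through igraph with all edge attributes preserved.
#'
#' @param net a `csgcn_network`.
#' @param path output path.
#' @param fmt `"tsv_edgelist"` or `"graphml"`.
#' @export
export_network <- function(net, path, fmt = c("tsv_edgelist", "graphml")) {
  fmt <- match.arg(fmt)
  if (fmt == "tsv_edgelist") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    g <- igraph::graph_from_data_frame(
      cbind(net$edges[, c("gene_a", "gene_b")],
            net$edges[, setdiff(names(net$edges),
                                c("gene_a", "gene_b", "source", "target")),
                      drop = FALSE]),
      directed = FALSE, vertices = net$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, fmt = c("tsv_edgelist", "graphml")) {
  fmt <- match.arg(fmt)
  if (fmt == "tsv_edgelist") {
    ed <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!nrow(ed))
      return(structure(list(nodes = character(), edges = ed,
                            conditions = list()), class = "csgcn_network"))
    ed$source <- ed$gene_a; ed$target <- ed$gene_b
    as_network(ed)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    ed <- igraph::as_data_frame(g, what = "edges")
    names(ed)[1:2] <- c("source", "target")
    as_network(ed)
  }
}

#' Load a published-style co-expression edge list
#'
#' Accepts any tab-delimited edge list whose first two columns (or columns
#' named `source`/`target` or `gene_a`/`gene_b`) are gene pairs; used for
#' summarizing externally provided networks.
#'
#' @param path TSV path.
#' @return a `csgcn_network`.
#' @export
load_network_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ed <- utils::read.delim(path, stringsAsFactors = FALSE)
  nm <- names(ed)
  if (all(c("gene_a", "gene_b") %in% nm)) {
    ed$source <- ed$gene_a; ed$target <- ed$gene_b
  } else if (!all(c("source", "target") %in% nm)) {
    names(ed)[1:2] <- c("source", "target")
  }
  as_network(ed)
}
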