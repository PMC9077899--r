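#' Load a TF -> target regulatory network from TSV
#'
#' Requires `tf` and `target` columns (optional `weight` carried through);
#' duplicated (tf, target) rows are collapsed with a message. Self-loops
#' are kept but flagged in `attr(, "self_loops")`.
#'
#' @param path TSV path.
#' @return data frame `tf`, `target`[, `weight`] of class `"grn"`.
#' @export
load_grn <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_grn(g)
}

#' @rdname load_grn
#' @param x data frame with `tf`, `target` columns.
#' @export
as_grn <- function(x) {
  if (!all(c("tf", "target") %in% names(x)))
    stop("GRN needs `tf` and `target` columns")
  key <- paste(x$tf, x$target, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    message(sum(dup), " duplicate regulatory edge(s) collapsed")
  out <- x[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "self_loops") <- which(out$tf == out$target)
  class(out) <- c("grn", class(out))
  out
}

#' Regulatory edges whose target lies in a subnetwork
#'
#' @param grn a `grn` data frame.
#' @param subnet a `csgcn_network` (one condition's subnetwork).
#' @return the subset of `grn` with `target` among `subnet` nodes.
#' @export
select_targeting_edges <- function(grn, subnet) {
  stopifnot(inherits(subnet, "csgcn_network"))
  out <- grn[grn$target %in% subnet$nodes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract TF triangle motifs over a condition subnetwork
#'
#' A motif is a TF regulating both endpoints of a co-expression edge: for
#' every subnetwork edge (a, b) and every TF with both tf->a and tf->b in
#' the regulatory network, one (tf, a, b) row is emitted (one row per
#' TF-edge incidence). Output is ordered lexicographically by
#' (tf, gene_a, gene_b). When `assessments` is supplied (from
#' [assess_regulatory_edges]), each motif is annotated with whether both
#' of its regulatory edges are doubly significant.
#'
#' @param grn a `grn` data frame.
#' @param subnet a condition `csgcn_network`.
#' @param assessments optional assessment table keyed by (tf, tr).
#' @return data frame `tf`, `gene_a`, `gene_b`, `condition`, `similarity`,
#'   `fully_significant` (NA without `assessments`).
#' @export
extract_triangles <- function(grn, subnet, assessments = NULL) {
  stopifnot(inherits(subnet, "csgcn_network"))
  cond <- if (length(subnet$conditions) == 1L) names(subnet$conditions) else NA
  ed <- subnet$edges
  if (!nrow(ed) || !nrow(grn)) {
    return(data.frame(tf = character(), gene_a = character(),
                      gene_b = character(), condition = character(),
                      similarity = numeric(), fully_significant = logical()))
  }
  targets_of <- split(grn$tf, grn$target)
  rows <- lapply(seq_len(nrow(ed)), function(i) {
    a <- ed$gene_a[i]; b <- ed$gene_b[i]
    tfs <- intersect(targets_of[[a]], targets_of[[b]])
    if (!length(tfs)) return(NULL)
    data.frame(tf = tfs, gene_a = a, gene_b = b,
               condition = if ("condition" %in% names(ed)) ed$condition[i] else cond,
               similarity = if ("similarity" %in% names(ed)) ed$similarity[i] else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(tf = character(), gene_a = character(),
                      gene_b = character(), condition = character(),
                      similarity = numeric(), fully_significant = logical()))
  out <- out[order(out$tf, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(assessments)) {
    akey <- paste(assessments$tf, assessments$tr)
    sig_a <- assessments$doubly_significant[match(paste(out$tf, out$gene_a), akey)]
    sig_b <- assessments$doubly_significant[match(paste(out$tf, out$gene_b), akey)]
    out$fully_significant <- !is.na(sig_a) & !is.na(sig_b) & sig_a & sig_b
  } else {
    out$fully_significant <- NA
  }
  out
}

#' Merge a co-expression subnetwork, its regulatory edges and motifs into
#' one annotated graph
#'
#' Builds a mixed graph for visualisation/export: undirected co-expression
#' edges (`edge_type = "coexpression"`) plus directed regulatory edges
#' (`edge_type = "regulatory"`, with `ratio_significant` when assessments
#' are given), node attributes `is_tf` and `de_direction`.
#'
#' @param subnet a condition `csgcn_network`.
#' @param grn_subset regulatory edges (e.g. from [select_targeting_edges]).
#' @param de optional [de_test] table for node DE direction.
#' @param assessments optional assessment table for edge significance.
#' @return an igraph (directed; co-expression edges are marked by
#'   `edge_type` and should be read as undirected).
#' @export
merge_for_export <- function(subnet, grn_subset, de = NULL,
                             assessments = NULL) {
  stopifnot(inherits(subnet, "csgcn_network"))
  co <- data.frame(from = subnet$edges$gene_a, to = subnet$edges$gene_b,
                   edge_type = "coexpression", ratio_significant = NA,
                   stringsAsFactors = FALSE)
  rg <- data.frame(from = grn_subset$tf, to = grn_subset$target,
                   edge_type = "regulatory", ratio_significant = NA,
                   stringsAsFactors = FALSE)
  if (!is.null(assessments) && nrow(rg)) {
    akey <- paste(assessments$tf, assessments$tr)
    rg$ratio_significant <-
      assessments$ratio_significant[match(paste(rg$from, rg$to), akey)]
  }
  edges <- rbind(co, rg)
  nodes <- data.frame(name = unique(c(edges$from, edges$to)),
                      stringsAsFactors = FALSE)
  nodes$is_tf <- nodes$name %in% grn_subset$tf
  nodes$de_direction <- "none"
  if (!is.null(de)) {
    ix <- match(nodes$name, de$gene)
    nodes$de_direction <- ifelse(is.na(ix), "none", de$direction[ix])
  }
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}
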