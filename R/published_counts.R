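#' Published lung-network count tables
#'
#' Node/edge counts of a published unified-lung condition-specific
#' co-expression network (full network plus four condition subnetworks)
#' and the published regulatory-edge category counts for the two
#' tumor-vs-normal comparisons. Shipped as plain-text data so the
#' package's summary arithmetic (mean degree 2E/N, uniqueness
#' percentages, category partition) can be exercised against real
#' published counts without any download.
#'
#' @return `published_network_counts()`: data frame `network`, `samples`,
#'   `nodes`, `edges`, `unique_nodes`, `unique_edges`,
#'   `clustering_coefficient`. `published_regulatory_counts()`: data
#'   frame `comparison`, `total`, `both_deg`, `ratio_significant`,
#'   `doubly_significant` and the four directional category counts.
#' @export
published_network_counts <- function() {
  utils::read.delim(system.file("extdata", "lung_network_attributes.tsv",
                                package = "csgcnreg"),
                    stringsAsFactors = FALSE)
}

#' @rdname published_network_counts
#' @export
published_regulatory_counts <- function() {
  utils::read.delim(system.file("extdata", "lung_regulatory_edge_counts.tsv",
                                package = "csgcnreg"),
                    stringsAsFactors = FALSE)
}

#' Derived attribute cells from published counts
#'
#' Recomputes, from the raw node/edge counts, every derived cell of the
#' published global-attribute table: mean degree 2E/N of each (sub)network
#' and of its unique part, and unique node/edge percentages, rounded
#' half-up to 2 decimals as displayed.
#'
#' @param counts a counts table shaped like [published_network_counts].
#' @return the input with `connectivity`, `unique_connectivity`,
#'   `unique_node_pct`, `unique_edge_pct` columns appended.
#' @export
derive_attribute_cells <- function(counts = published_network_counts()) {
  counts$connectivity <-
    round_half_up(avg_connectivity(counts$nodes, counts$edges), 2)
  counts$unique_connectivity <- round_half_up(
    ifelse(is.na(counts$unique_nodes), NA,
           avg_connectivity(counts$unique_nodes, counts$unique_edges)), 2)
  counts$unique_node_pct <-
    round_half_up(100 * counts$unique_nodes / counts$nodes, 2)
  counts$unique_edge_pct <-
    round_half_up(100 * counts$unique_edges / counts$edges, 2)
  counts
}
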