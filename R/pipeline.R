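#' Run the full biomarker-system pipeline
#'
#' Normalization and QC, condition-specific network construction,
#' per-comparison differential expression and TF/TR ratio testing,
#' regulatory-edge categorization, triangle-motif extraction, and
#' MLP validation of each condition's triangle gene set. Stage outputs
#' are returned in-memory and, when `out_dir` is given, also written as
#' tab-delimited files plus an effective-parameter manifest, so any stage
#' can be re-run from its predecessor's file.
#'
#' @param gem a [gem]; linear-scale input is log2 quantile-normalized
#'   first, log2 input is used as-is.
#' @param annot annotation data frame.
#' @param grn optional regulatory network (`tf`, `target` data frame).
#' @param comparisons data frame with `cond_a` (reference) and `cond_b`
#'   columns; default compares the first condition (alphabetically) to
#'   each other condition.
#' @param params a [csgcn_params].
#' @param pairs optional gene-pair restriction passed to [build_csgcn].
#' @param classify run the MLP validation stage (default TRUE when a GRN
#'   yields triangles).
#' @param seed integer seed (classifier split/initialisation).
#' @param ks_threshold KS outlier flag threshold.
#' @param out_dir optional output directory.
#' @return list of class `"csgcn_pipeline"` with elements `gem`
#'   (normalized), `ks`, `edges`, `network`, `attributes`, `de`, `ratio`,
#'   `assessments`, `counts`, `triangles`, `classification`, `params`.
#' @export
run_pipeline <- function(gem, annot, grn = NULL, comparisons = NULL,
                         params = csgcn_params(), pairs = NULL,
                         classify = TRUE, seed = 1L, ks_threshold = 0.15,
                         out_dir = NULL) {
  stopifnot(is_gem(gem))
  check_annotation(gem, annot)
  if (gem$scale == "linear") gem <- log2_quantile_normalize(gem)
  ks <- ks_outlier_detect(gem, threshold = ks_threshold)

  edges <- build_csgcn(gem, annot, params = params, pairs = pairs)
  net <- as_network(edges)
  attributes <- network_attribute_table(net)

  conds <- sort(unique(annot$condition))
  if (is.null(comparisons) && length(conds) >= 2)
    comparisons <- data.frame(cond_a = conds[1], cond_b = conds[-1],
                              stringsAsFactors = FALSE)

  de <- list(); ratio <- list(); assessments <- list()
  counts <- list(); triangles <- list(); classification <- list()
  if (!is.null(grn)) grn <- as_grn(grn)

  for (i in seq_len(NROW(comparisons))) {
    ca <- comparisons$cond_a[i]; cb <- comparisons$cond_b[i]
    cmp <- paste0(cb, "_vs_", ca)
    de[[cmp]] <- de_test(gem, annot, ca, cb, alpha = params$alpha)
    if (is.null(grn) || !cb %in% names(net$conditions)) next
    subnet <- extract_condition_subnetwork(net, cb)
    targeting <- select_targeting_edges(grn, subnet)
    if (!nrow(targeting)) next
    ratio[[cmp]] <- ratio_test_edges(gem, targeting, annot, ca, cb,
                                     alpha = params$alpha)
    asm <- assess_regulatory_edges(targeting, de[[cmp]], ratio[[cmp]])
    assessments[[cmp]] <- asm$assessments
    counts[[cmp]] <- cbind(data.frame(comparison = cmp), asm$counts)
    triangles[[cmp]] <- extract_triangles(targeting, subnet,
                                          asm$assessments)
    if (classify && nrow(triangles[[cmp]])) {
      gene_set <- unique(c(triangles[[cmp]]$tf, triangles[[cmp]]$gene_a,
                           triangles[[cmp]]$gene_b))
      classification[[cmp]] <- train_evaluate(
        subset_gem(gem, gene_set), annot,
        classifier_config(seed = seed))
    }
  }
  counts <- if (length(counts)) do.call(rbind, counts) else NULL
  if (!is.null(counts)) rownames(counts) <- NULL

  result <- structure(list(gem = gem, ks = ks, edges = edges, network = net,
                           attributes = attributes, de = de, ratio = ratio,
                           assessments = assessments, counts = counts,
                           triangles = triangles,
                           classification = classification,
                           params = params, seed = seed),
                      class = "csgcn_pipeline")
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

write_pipeline <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE, na = "NA")
  write_gem(result$gem, file.path(out_dir, "normalized_gem.tsv"))
  wt(result$ks, "ks_flags.tsv")
  write_edges(result$edges, file.path(out_dir, "csgcn_edges.tsv"))
  wt(result$attributes, "network_attributes.tsv")
  for (cmp in names(result$de)) wt(result$de[[cmp]], paste0("de_", cmp, ".tsv"))
  for (cmp in names(result$ratio)) wt(result$ratio[[cmp]], paste0("ratio_", cmp, ".tsv"))
  for (cmp in names(result$assessments))
    wt(result$assessments[[cmp]], paste0("regulatory_assessment_", cmp, ".tsv"))
  if (!is.null(result$counts)) wt(result$counts, "regulatory_edge_counts.tsv")
  for (cmp in names(result$triangles))
    wt(result$triangles[[cmp]], paste0("triangles_", cmp, ".tsv"))
  for (cmp in names(result$classification)) {
    rep <- result$classification[[cmp]]
    wt(as.data.frame.matrix(rep$confusion), paste0("confusion_", cmp, ".tsv"))
  }
  p <- result$params
  manifest <- data.frame(parameter = c(names(p), "seed"),
                         value = c(unlist(p, use.names = FALSE), result$seed))
  wt(manifest, "manifest.tsv")
  invisible(out_dir)
}

#' @export
print.csgcn_pipeline <- function(x, ...) {
  cat("csGCN pipeline result\n")
  cat(sprintf("  edges: %d (conditions: %s)\n", nrow(x$edges),
              paste(names(x$network$conditions), collapse = ", ")))
  for (cmp in names(x$triangles))
    cat(sprintf("  %s: %d triangle motif(s)\n", cmp, nrow(x$triangles[[cmp]])))
  invisible(x)
}
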