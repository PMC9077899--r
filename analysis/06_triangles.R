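#!/usr/bin/env Rscript
# Stage 6: triangle biomarker systems. A triangle is a TF regulating both
# endpoints of a condition-specific co-expression edge; it is fully
# significant when both of its regulatory edges are doubly significant
# (both genes DEGs and a shifted TF/TR ratio). The merged co-expression +
# regulatory graph is exported for network viewers.

suppressMessages(library(csgcnreg))

edges <- load_edges(file.path("results", "csgcn_edges.tsv"))
net <- as_network(edges)
grn <- load_grn(file.path("results", "fixture", "grn.tsv"))

for (cb in c("tumor_a", "tumor_b")) {
  cmp <- paste0(cb, "_vs_normal_", substr(cb, 7, 7))
  if (!cb %in% names(net$conditions)) next
  subnet <- extract_condition_subnetwork(net, cb)
  asm_path <- file.path("results", paste0("regulatory_assessment_", cmp, ".tsv"))
  asm <- if (file.exists(asm_path)) read.delim(asm_path) else NULL
  targeting <- select_targeting_edges(grn, subnet)
  tri <- extract_triangles(targeting, subnet, asm)
  write.table(tri, file.path("results", paste0("triangles_", cb, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d triangle(s), %d fully significant\n", cb, nrow(tri),
              sum(tri$fully_significant, na.rm = TRUE)))
  if (nrow(tri)) {
    de <- read.delim(file.path("results", paste0("de_", cmp, ".tsv")))
    merged <- merge_for_export(subnet, targeting, de = de, assessments = asm)
    igraph::write_graph(merged,
                        file.path("results", paste0("merged_", cb, ".graphml")),
                        format = "graphml")
  }
}
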