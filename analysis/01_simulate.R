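#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-condition expression study.
#
# 200 genes, four conditions (two "normal", two "tumor") with 100 samples
# each; 20 planted condition-specific co-expression pairs (Spearman 0.85),
# four TFs whose coupling to their targets exists only in one condition,
# planted DEGs, and structured missingness on two genes. Everything
# downstream is scored against the truth manifest written here.

suppressMessages(library(csgcnreg))

seed <- 17L
out_dir <- file.path("results", "fixture")

bundle <- default_bundle(
  samples_per_condition = c(normal_a = 100, normal_b = 100,
                            tumor_a = 100, tumor_b = 100),
  seed = seed)
paths <- write_fixture(bundle, out_dir)

cat("Synthetic study written to", out_dir, "\n")
print(bundle$gem)
cat(sprintf("planted co-expression edges: %d | regulatory edges: %d | DEGs: %d\n",
            nrow(bundle$truth$planted_edges), nrow(bundle$grn),
            nrow(bundle$truth$planted_degs)))
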