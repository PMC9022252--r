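#!/usr/bin/env Rscript
# Preprocessing: drop probes without a unique gene mapping, flag and remove
# outlier samples on the first two principal components, and collapse
# multi-probe genes to gene-level values by the per-sample median.

suppressPackageStartupMessages(library(stagenet))

expr <- read_expression("results/data/expression.tsv")
meta <- read_metadata("results/data/metadata.tsv")
annot <- read_annotation("results/data/probes.tsv")

cat("input:", nrow(expr), "probes x", ncol(expr), "samples\n")
expr <- drop_unmapped_probes(expr, annot)
cat("after unique-mapping filter:", nrow(expr), "probes\n")

outliers <- detect_outlier_samples(expr, k = 5)
cat("outlier samples flagged:", paste(outliers, collapse = ", "), "\n")
expr <- expr[, !colnames(expr) %in% outliers, drop = FALSE]
meta <- meta[!meta$sample_id %in% outliers, , drop = FALSE]

gene_expr <- collapse_probes(expr, annot)
cat("gene-level matrix:", nrow(gene_expr), "genes x", ncol(gene_expr),
    "samples\n")

dir.create("results", showWarnings = FALSE)
write_expression(expr, "results/probe_expression_clean.tsv",
                 id_col = "probe_id")
write_expression(gene_expr, "results/gene_expression.tsv", id_col = "gene")
write_metadata(meta, "results/metadata_clean.tsv")
writeLines(outliers, "results/outlier_samples.txt")
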