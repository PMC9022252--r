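#!/usr/bin/env Rscript
# Stage-specific correlation networks over the master DEG list: per-stage
# critical |PCC| from the two-sided test at p = 0.001 and df = n - 2, then
# weighted, unweighted and stage-unique networks.

suppressPackageStartupMessages(library(stagenet))

gene_expr <- read_expression("results/gene_expression.tsv")
meta <- read_metadata("results/metadata_clean.tsv")
master <- readLines("results/master_deg_list.txt")
stage_of <- setNames(meta$stage, meta$sample_id)
mm <- gene_expr[rownames(gene_expr) %in% master, , drop = FALSE]

cat(sprintf("%-8s %10s %10s %8s\n", "stage", "n_samples", "r_th", "edges"))
nets <- list()
for (s in STAGES) {
  sm <- mm[, stage_of[colnames(mm)] == s, drop = FALSE]
  nets[[s]] <- build_stage_network(sm, p = 0.001, weighted = TRUE, stage = s)
  un <- build_stage_network(sm, p = 0.001, weighted = FALSE, stage = s)
  stopifnot(nrow(un$edges) == nrow(nets[[s]]$edges))
  cat(sprintf("%-8s %10d %10.4f %8d\n", s, ncol(sm), nets[[s]]$r_th,
              nrow(nets[[s]]$edges)))
  write_network_tsv(nets[[s]], file.path("results",
                                         paste0("network_", s, ".tsv")))
  write_network_graphml(nets[[s]],
                        file.path("results",
                                  paste0("network_", s, ".graphml")))
}

for (s in STAGES) {
  u <- stage_unique_network(nets[[s]], nets[setdiff(STAGES, s)])
  cat("stage-unique", s, ":", nrow(u$edges), "edges\n")
  write_network_tsv(u, file.path("results",
                                 paste0("network_unique_", s, ".tsv")))
}
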