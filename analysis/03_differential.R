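#!/usr/bin/env Rscript
# Differential expression between neighboring stages (Welch t per probe,
# geometric-mean aggregation to genes), the master DEG list, and
# stage-specific biomarkers (four-way DEG intersections).

suppressPackageStartupMessages(library(stagenet))

expr <- read_expression("results/probe_expression_clean.tsv")
meta <- read_metadata("results/metadata_clean.tsv")
annot <- read_annotation("results/data/probes.tsv")

deg <- neighboring_deg(expr, meta, annot)
for (nm in names(deg)) {
  write_differential(deg[[nm]], file.path("results",
                                          paste0("deg_", nm, ".tsv")))
  cat(sprintf("%-12s %5d genes tested, %4d DEGs at p <= 0.05\n", nm,
              nrow(deg[[nm]]), sum(deg[[nm]]$p_value <= 0.05)))
}

master <- master_deg_list(deg, alpha = 0.05)
writeLines(master, "results/master_deg_list.txt")
cat("master DEG list:", length(master), "genes\n")

for (s in c("I", "II", "III", "IV")) {
  bio <- stage_specific_biomarkers(expr, meta, s, alpha = 0.05,
                                   annotation = annot)
  writeLines(bio, file.path("results",
                            paste0("biomarkers_stage_", s, ".txt")))
  cat("stage", s, "specific biomarkers:", length(bio), "\n")
}
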