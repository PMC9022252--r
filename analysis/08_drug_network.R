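#!/usr/bin/env Rscript
# Supervised key-gene subnetworks (PPI score >= 0.4, up to 20 neighbors per
# key gene) and the drug-target-PPI network (PPI score >= 0.9) annotated with
# per-stage gene weights and log2 fold-changes, from the shipped synthetic
# drug-target and PPI snapshots.

suppressPackageStartupMessages(library(stagenet))

master <- readLines("results/master_deg_list.txt")
meta <- read_metadata("results/metadata_clean.tsv")
nets <- lapply(setNames(STAGES, STAGES), function(s)
  stage_network(read.delim(file.path("results",
                                     paste0("network_", s, ".tsv"))),
                stage = s))
ppi <- read_edges(system.file("extdata", "ppi_synthetic.tsv",
                              package = "stagenet"))
targets <- read_drug_targets(system.file("extdata",
                                         "drug_targets_synthetic.tsv",
                                         package = "stagenet"))
fc <- lapply(setNames(names(neighboring_comparisons()),
                      names(neighboring_comparisons())), function(nm) {
  r <- read.delim(file.path("results", paste0("deg_", nm, ".tsv")))
  setNames(r$log2fc, r$gene)
})

key_genes <- c("G0001", "G0041", "G0081")
for (s in c("I", "II")) {
  sub <- extract_key_subnetwork(key_genes, ppi, master, nets[[s]],
                                score_min = 0.4, max_neighbors = 20L)
  cat("key-gene subnetwork, stage", s, ":", length(sub$nodes), "nodes,",
      nrow(sub$edges), "edges\n")
  write_network_graphml(sub, file.path("results",
                                       paste0("key_subnetwork_", s,
                                              ".graphml")))
}

dn <- build_drug_network(targets, ppi, nets, fc = fc, master = master,
                         ppi_score_min = 0.9,
                         gene_sets = read_gmt("results/data/gene_sets.gmt"))
print(dn)
write_drug_network_graphml(dn, "results/drug_network.graphml")
write_drug_network_json(dn, "results/drug_network.json")
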