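#!/usr/bin/env Rscript
# Edge-based hypergeometric enrichment of the gene-set collection on the
# stage-specific and stage-unique networks. The planted blocks should light
# up; the random decoy set should not.

suppressPackageStartupMessages(library(stagenet))

master <- readLines("results/master_deg_list.txt")
sets <- read_gmt("results/data/gene_sets.gmt")
load_net <- function(f, s) stage_network(read.delim(f), stage = s)
nets <- c(
  lapply(setNames(STAGES, STAGES), function(s)
    load_net(file.path("results", paste0("network_", s, ".tsv")), s)),
  lapply(setNames(STAGES, paste0("unique_", STAGES)), function(s)
    load_net(file.path("results", paste0("network_unique_", s, ".tsv")), s)))

tab <- enrich_networks(nets, sets, master, alpha = 0.05)
write.table(tab, "results/edge_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("significant (network, set) pairs at p <= 0.05:\n")
print(tab[tab$significant, c("network", "set", "d_set", "k", "p_value")],
      row.names = FALSE)

gene_tab <- enrich_genes(nets[STAGES], sets, master, alpha = 0.05)
write.table(gene_tab, "results/gene_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
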