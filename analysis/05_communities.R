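#!/usr/bin/env Rscript
# Louvain communities per stage network, the cross-stage NMI matrix, and
# degree-preserving permutation tests for the neighboring stage pairs.

suppressPackageStartupMessages(library(stagenet))

meta <- read_metadata("results/metadata_clean.tsv")
nets <- lapply(setNames(STAGES, STAGES), function(s) {
  e <- read.delim(file.path("results", paste0("network_", s, ".tsv")))
  stage_network(e, stage = s)
})

set.seed(20260919L)
seeds <- sample.int(.Machine$integer.max, 8L)
for (i in seq_along(STAGES)) {
  s <- STAGES[i]
  p <- louvain(nets[[s]], seed = seeds[i])
  cat(sprintf("stage %-7s %3d communities, Q = %.3f\n", s,
              length(unique(p$membership)), p$modularity))
  write_partition(p, file.path("results", paste0("communities_", s, ".tsv")))
}

M <- nmi_matrix(nets, seed = seeds[6L])
write.table(round(M, 4), "results/nmi_matrix.tsv", sep = "\t", quote = FALSE,
            col.names = NA)
cat("\nNMI matrix across stages:\n")
print(round(M, 4))

perm <- list()
pairs <- list(c("I", "II"), c("II", "III"))
for (pi in seq_along(pairs)) {
  pair <- pairs[[pi]]
  pt <- nmi_permutation_test(nets[[pair[1]]], nets[[pair[2]]],
                             n_perm = 999L, seed = seeds[6L + pi])
  cat(sprintf("stages %s vs %s: observed NMI %.4f, permutation p = %.4g\n",
              pair[1], pair[2], pt$observed_nmi, pt$p_value))
  perm[[paste(pair, collapse = "_vs_")]] <-
    list(observed_nmi = pt$observed_nmi, p_value = pt$p_value,
         n_perm = pt$n_perm, null_mean = mean(pt$null_nmis),
         null_max = max(pt$null_nmis))
}
jsonlite::write_json(perm, "results/nmi_permutation.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
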