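# Small graph and dataset builders shared by the tests.

unit_edges <- function(a, b) {
  data.frame(gene_a = a, gene_b = b, weight = 1, stringsAsFactors = FALSE)
}

clique_edges <- function(ids) {
  pairs <- t(utils::combn(ids, 2L))
  unit_edges(pairs[, 1L], pairs[, 2L])
}

two_cliques_bridge <- function(k = 5L) {
  a <- sprintf("a%02d", seq_len(k))
  b <- sprintf("b%02d", seq_len(k))
  stage_network(rbind(clique_edges(a), clique_edges(b),
                      unit_edges(a[1L], b[1L])))
}

# Erdos-Renyi G(n, p) network with unit weights.
gnp_network <- function(n, p, seed, prefix = "n") {
  set.seed(seed)
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  pairs <- t(utils::combn(ids, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  stage_network(unit_edges(pairs[keep, 1L], pairs[keep, 2L]), nodes = ids)
}

# Compact simulation used where a full-sized cohort is not needed.
small_sim <- function(seed = 1L, ...) {
  generate_dataset(sim_config(n_genes = 60L, n_blocks = 2L, block_size = 15L,
                              trend_genes = c(`monotone-up` = 5L,
                                              `monotone-down` = 5L),
                              n_outliers = 0L, frac_unmapped = 0,
                              seed = seed, ...))
}

gene_level <- function(ds) {
  collapse_probes(drop_unmapped_probes(ds$expression, ds$annotation),
                  ds$annotation)
}

stage_submatrix <- function(mat, metadata, stage) {
  st <- setNames(metadata$stage, metadata$sample_id)
  mat[, !is.na(st[colnames(mat)]) & st[colnames(mat)] == stage, drop = FALSE]
}
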