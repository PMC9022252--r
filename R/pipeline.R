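#' Pipeline configuration
#'
#' Collects input paths and the analysis parameters. The defaults are the
#' pipeline's operating point: DEG cut-off 0.05, edge p-value 0.001, 1000
#' permutations, 60 model profiles with maximum unit change 1, PPI score
#' thresholds 0.4 (key-gene subnetworks) and 0.9 (drug network), at most 20
#' PPI neighbors per key gene.
#'
#' @param expression,metadata,annotation Paths to the expression matrix,
#'   sample metadata and probe annotation TSVs.
#' @param gene_sets Optional GMT path.
#' @param ppi Optional scored PPI edge-list path.
#' @param drug_targets Optional drug-target TSV path.
#' @param key_genes Optional character vector of key genes for supervised
#'   subnetwork extraction.
#' @param out_dir Output directory.
#' @param alpha_deg DEG p-value cut-off (default 0.05).
#' @param p_edge Correlation-edge p-value threshold (default 0.001).
#' @param n_perm Permutations for the NMI test (default 1000).
#' @param stem_profiles Number of model profiles (default 60).
#' @param stem_max_change Maximum unit change of a profile (default 1).
#' @param ppi_score_subnet PPI score threshold for key-gene subnetworks
#'   (default 0.4).
#' @param ppi_score_drug PPI score threshold for the drug network
#'   (default 0.9).
#' @param max_neighbors Neighbor cap per key gene (default 20).
#' @param outlier_k Robust z cut-off for sample outlier removal (default 5).
#' @param seed Top-level seed; all stage seeds derive from it.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, metadata, annotation = NULL,
                            gene_sets = NULL, ppi = NULL, drug_targets = NULL,
                            key_genes = NULL, out_dir = "stagenet_out",
                            alpha_deg = 0.05, p_edge = 0.001, n_perm = 1000L,
                            stem_profiles = 60L, stem_max_change = 1L,
                            ppi_score_subnet = 0.4, ppi_score_drug = 0.9,
                            max_neighbors = 20L, outlier_k = 5, seed = 1L) {
  cfg <- as.list(environment())
  if (alpha_deg <= 0 || alpha_deg > 1) stop("alpha_deg must be in (0, 1]")
  if (p_edge <= 0 || p_edge > 1) stop("p_edge must be in (0, 1]")
  if (n_perm < 1L) stop("n_perm must be at least 1")
  if (stem_profiles < 1L) stop("stem_profiles must be at least 1")
  if (stem_max_change < 1L) stop("stem_max_change must be at least 1")
  for (f in c("ppi_score_subnet", "ppi_score_drug"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  if (max_neighbors < 1L) stop("max_neighbors must be at least 1")
  class(cfg) <- "pipeline_config"
  cfg
}

#' The pipeline's default analysis parameters
#'
#' @return Named list of the default thresholds used throughout the pipeline.
#' @export
default_parameters <- function() {
  list(alpha_deg = 0.05, p_edge = 0.001, n_perm = 1000L, stem_profiles = 60L,
       stem_max_change = 1L, ppi_score_subnet = 0.4, ppi_score_drug = 0.9,
       max_neighbors = 20L)
}

#' Run the full stage-network analysis pipeline
#'
#' Stages, in order: read inputs; drop unmapped probes; remove outlier
#' samples; collapse probes to genes; neighboring-stage differential
#' expression and the master DEG list; stage-specific (weighted and
#' unweighted) and stage-unique correlation networks; Louvain communities and
#' the cross-stage NMI matrix with degree-preserving permutation tests for
#' the neighboring pairs; edge-based gene-set enrichment; trend profiling and
#' stage-specific biomarkers; optional key-gene subnetworks and the
#' drug-target-PPI network. Every artifact is written under `out_dir` and a
#' JSON manifest records parameters, input checksums and seeds.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, 16L)
  out <- function(...) file.path(config$out_dir, ...)

  expr <- read_expression(config$expression)
  meta <- read_metadata(config$metadata)
  annot <- if (!is.null(config$annotation)) read_annotation(config$annotation)
  missing_meta <- setdiff(colnames(expr), meta$sample_id)
  if (length(missing_meta))
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "))

  # preprocess: unique probes, outlier removal, gene collapse
  if (!is.null(annot)) expr <- drop_unmapped_probes(expr, annot)
  outliers <- detect_outlier_samples(expr, k = config$outlier_k)
  if (length(outliers)) {
    expr <- expr[, !colnames(expr) %in% outliers, drop = FALSE]
    meta <- meta[!meta$sample_id %in% outliers, , drop = FALSE]
  }
  writeLines(outliers, out("outlier_samples.txt"))
  gene_expr <- if (!is.null(annot)) collapse_probes(expr, annot) else expr
  write_expression(gene_expr, out("gene_expression.tsv"), id_col = "gene")

  # differential expression along the chain; master DEG list
  deg <- neighboring_deg(expr, meta, annot)
  for (nm in names(deg)) write_differential(deg[[nm]], out(paste0("deg_", nm, ".tsv")))
  master <- master_deg_list(deg, alpha = config$alpha_deg)
  writeLines(master, out("master_deg_list.txt"))
  fc <- lapply(deg, function(r) setNames(r$log2fc, r$gene))

  # stage networks over the master list
  stage_of <- setNames(meta$stage, meta$sample_id)
  mastermat <- gene_expr[rownames(gene_expr) %in% master, , drop = FALSE]
  nets <- list(); unets <- list()
  for (s in STAGES) {
    cols <- colnames(mastermat)[stage_of[colnames(mastermat)] == s]
    sm <- mastermat[, cols, drop = FALSE]
    nets[[s]] <- build_stage_network(sm, p = config$p_edge, weighted = TRUE,
                                     stage = s)
    unets[[s]] <- build_stage_network(sm, p = config$p_edge, weighted = FALSE,
                                      stage = s)
    write_network_tsv(nets[[s]], out(paste0("network_", s, ".tsv")))
    write_network_graphml(nets[[s]], out(paste0("network_", s, ".graphml")))
  }
  uniq <- lapply(STAGES, function(s)
    stage_unique_network(nets[[s]], nets[setdiff(STAGES, s)]))
  names(uniq) <- STAGES
  for (s in STAGES)
    write_network_tsv(uniq[[s]], out(paste0("network_unique_", s, ".tsv")))

  # communities and cross-stage comparison
  parts <- list()
  for (i in seq_along(STAGES)) {
    s <- STAGES[i]
    if (nrow(nets[[s]]$edges)) {
      parts[[s]] <- louvain(nets[[s]], seed = seeds[i])
      write_partition(parts[[s]], out(paste0("communities_", s, ".tsv")))
    }
  }
  with_edges <- names(parts)
  nmi_tab <- nmi_matrix(nets[with_edges], seed = seeds[6L])
  write.table(nmi_tab, out("nmi_matrix.tsv"), sep = "\t", quote = FALSE,
              col.names = NA)
  perm <- list()
  pairs <- list(c("I", "II"), c("II", "III"))
  for (pi in seq_along(pairs)) {
    pair <- pairs[[pi]]
    if (!all(pair %in% with_edges)) next
    pt <- nmi_permutation_test(nets[[pair[1L]]], nets[[pair[2L]]],
                               n_perm = config$n_perm,
                               seed = seeds[6L + pi])
    perm[[paste(pair, collapse = "_vs_")]] <-
      list(observed_nmi = pt$observed_nmi, p_value = pt$p_value,
           n_perm = pt$n_perm,
           null_mean = mean(pt$null_nmis), null_max = max(pt$null_nmis))
  }
  jsonlite::write_json(perm, out("nmi_permutation.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  # enrichment
  sets <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets)
  if (!is.null(sets)) {
    enr <- enrich_networks(c(nets[with_edges],
                             setNames(uniq[with_edges],
                                      paste0("unique_", with_edges))),
                           sets, master, alpha = config$alpha_deg)
    write.table(enr, out("edge_enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  # trends and stage-specific biomarkers
  tr <- trend_analysis(gene_expr, meta, m = config$stem_profiles,
                       c = config$stem_max_change)
  write.table(tr$assignments, out("trend_assignments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  bio <- lapply(STAGES[-1L], function(s)
    stage_specific_biomarkers(expr, meta, s, alpha = config$alpha_deg,
                              annotation = annot))
  names(bio) <- STAGES[-1L]
  jsonlite::write_json(bio, out("stage_specific_biomarkers.json"),
                       pretty = TRUE)

  # supervised key-gene subnetworks and the drug network
  ppi <- if (!is.null(config$ppi)) read_edges(config$ppi)
  if (!is.null(ppi) && length(config$key_genes)) {
    for (s in with_edges) {
      sub <- extract_key_subnetwork(config$key_genes, ppi, master, nets[[s]],
                                    score_min = config$ppi_score_subnet,
                                    max_neighbors = config$max_neighbors)
      write_network_graphml(sub, out(paste0("key_subnetwork_", s, ".graphml")))
    }
  }
  if (!is.null(ppi) && !is.null(config$drug_targets)) {
    dn <- build_drug_network(read_drug_targets(config$drug_targets), ppi,
                             nets[with_edges], fc = fc, master = master,
                             ppi_score_min = config$ppi_score_drug,
                             gene_sets = sets)
    write_drug_network_graphml(dn, out("drug_network.graphml"))
    write_drug_network_json(dn, out("drug_network.json"))
  }

  input_paths <- unlist(cfg_paths <- config[c("expression", "metadata",
                                              "annotation", "gene_sets",
                                              "ppi", "drug_targets")])
  manifest <- list(
    parameters = config[c("alpha_deg", "p_edge", "n_perm", "stem_profiles",
                          "stem_max_change", "ppi_score_subnet",
                          "ppi_score_drug", "max_neighbors", "outlier_k")],
    seed = config$seed, stage_seeds = seeds,
    inputs = as.list(tools::md5sum(input_paths)),
    outliers_removed = outliers,
    n_master_degs = length(master),
    edges_per_stage = vapply(nets, function(n) nrow(n$edges), integer(1L)),
    r_th_per_stage = vapply(nets, function(n) n$r_th, numeric(1L)),
    modularity_per_stage = vapply(parts, function(p) p$modularity,
                                  numeric(1L)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
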