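#' Read a drug-target table
#'
#' @param path TSV with columns `drug`, `gene`.
#' @return Data frame with character columns `drug`, `gene`; duplicate
#'   (drug, gene) pairs are collapsed with a warning.
#' @export
read_drug_targets <- function(path) {
  if (!file.exists(path)) stop("drug-target file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, fill = FALSE)
  if (!all(c("drug", "gene") %in% colnames(df)))
    stop("drug-target table must have columns drug, gene: ", path)
  df$drug <- as.character(df$drug)
  df$gene <- as.character(df$gene)
  dup <- duplicated(df[, c("drug", "gene")])
  if (any(dup)) {
    warning("collapsing ", sum(dup), " duplicate drug-target pair(s)")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df[, c("drug", "gene")]
}

#' Assemble the drug-target-PPI network
#'
#' Nodes are drugs and their target genes restricted to the master DEG list
#' (targets outside the master list are dropped with a warning; drugs left
#' with no targets are retained and flagged). Gene-gene edges come from the
#' PPI snapshot at score >= `ppi_score_min` between retained targets. Each
#' gene node is annotated with its per-stage gene weight (sum of incident
#' |PCC| edge weights in that stage's network) and per-stage log2 fold-change.
#'
#' @param targets Data frame from [read_drug_targets()].
#' @param ppi Scored edge list from [read_edges()].
#' @param stage_nets Named list of weighted [stage_network()]s.
#' @param fc Named list (by stage) of named numeric log2fc vectors (gene ->
#'   log2fc vs normal), or NULL.
#' @param master Character vector: master DEG list.
#' @param ppi_score_min Minimum PPI score (default 0.9).
#' @param gene_sets Optional named list of gene sets; membership is emitted
#'   as a `pathways` node annotation.
#' @return List of class `drug_network` with `nodes`, `edges`, `gene_attrs`.
#' @export
build_drug_network <- function(targets, ppi, stage_nets, fc = NULL, master,
                               ppi_score_min = 0.9, gene_sets = NULL) {
  dropped <- setdiff(unique(targets$gene), master)
  if (length(dropped))
    warning("dropping target gene(s) absent from the master list: ",
            paste(dropped, collapse = ", "))
  kept <- targets[targets$gene %in% master, , drop = FALSE]
  drugs <- sort(unique(targets$drug))
  tgenes <- sort(unique(kept$gene))
  degree0 <- !drugs %in% kept$drug

  nodes <- rbind(
    data.frame(id = drugs, type = "drug", no_targets = degree0,
               stringsAsFactors = FALSE),
    data.frame(id = tgenes, type = "gene", no_targets = FALSE,
               stringsAsFactors = FALSE))

  dt_edges <- if (nrow(kept)) {
    data.frame(from = kept$drug, to = kept$gene, type = "drug_target",
               score = NA_real_, stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0L), to = character(0L),
               type = character(0L), score = numeric(0L),
               stringsAsFactors = FALSE)
  }
  pp <- ppi[ppi$score >= ppi_score_min &
              ppi$gene_a %in% tgenes & ppi$gene_b %in% tgenes, ,
            drop = FALSE]
  ppi_edges <- if (nrow(pp)) {
    data.frame(from = pp$gene_a, to = pp$gene_b, type = "ppi",
               score = pp$score, stringsAsFactors = FALSE)
  } else dt_edges[0L, ]
  edges <- rbind(dt_edges, ppi_edges)

  gene_attrs <- data.frame(gene = tgenes, stringsAsFactors = FALSE)
  for (s in names(stage_nets)) {
    w <- gene_weights(stage_nets[[s]])
    gene_attrs[[paste0("weight_", s)]] <-
      ifelse(tgenes %in% names(w), unname(w[tgenes]), 0)
  }
  if (!is.null(fc)) {
    for (s in names(fc))
      gene_attrs[[paste0("log2fc_", s)]] <- unname(fc[[s]][tgenes])
  }
  if (!is.null(gene_sets)) {
    gene_attrs$pathways <- vapply(tgenes, function(g)
      paste(names(gene_sets)[vapply(gene_sets, function(x) g %in% x,
                                    logical(1L))], collapse = ","),
      character(1L))
  }
  structure(list(nodes = nodes, edges = edges, gene_attrs = gene_attrs),
            class = "drug_network")
}

#' @export
print.drug_network <- function(x, ...) {
  cat("drug_network:", sum(x$nodes$type == "drug"), "drugs,",
      sum(x$nodes$type == "gene"), "target genes,",
      sum(x$edges$type == "drug_target"), "drug-target edges,",
      sum(x$edges$type == "ppi"), "PPI edges\n")
  invisible(x)
}

#' Write a drug-target-PPI network as GraphML
#'
#' @param dn A [build_drug_network()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_network_graphml <- function(dn, path) {
  vert <- dn$nodes
  m <- match(vert$id, dn$gene_attrs$gene)
  for (col in setdiff(colnames(dn$gene_attrs), "gene")) {
    v <- dn$gene_attrs[[col]][m]
    if (is.numeric(v)) v[is.na(v)] <- 0
    vert[[col]] <- v
  }
  names(vert)[names(vert) == "id"] <- "name"
  g <- igraph::graph_from_data_frame(dn$edges, directed = FALSE,
                                     vertices = vert)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a JSON summary of a drug-target-PPI network
#'
#' @inheritParams write_drug_network_graphml
#' @return `path`, invisibly.
#' @export
write_drug_network_json <- function(dn, path) {
  jsonlite::write_json(
    list(n_drugs = sum(dn$nodes$type == "drug"),
         n_target_genes = sum(dn$nodes$type == "gene"),
         n_drug_target_edges = sum(dn$edges$type == "drug_target"),
         n_ppi_edges = sum(dn$edges$type == "ppi"),
         flagged_drugs = dn$nodes$id[dn$nodes$no_targets],
         gene_attrs = dn$gene_attrs),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
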