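#' Construct a stage network object
#'
#' Undirected weighted graph over genes, stored as a canonical edge list
#' (`gene_a < gene_b`, each pair once, no self-loops) plus threshold metadata.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `weight`.
#' @param nodes Character vector of node ids (defaults to the genes appearing
#'   in `edges`).
#' @param stage Stage label carried as metadata.
#' @param r_th Critical correlation used to threshold edges.
#' @param weighted Logical; unweighted networks carry weight 1 on every edge.
#' @return Object of class `stage_network`.
#' @export
stage_network <- function(edges, nodes = NULL, stage = NA_character_,
                          r_th = 0, weighted = TRUE) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(gene_a = character(0L), gene_b = character(0L),
                        weight = numeric(0L), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(gene_a = as.character(edges$gene_a),
                        gene_b = as.character(edges$gene_b),
                        weight = as.numeric(edges$weight),
                        stringsAsFactors = FALSE)
    if (any(edges$gene_a == edges$gene_b)) stop("self-loops are not allowed")
    swap <- edges$gene_a > edges$gene_b
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
    key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  structure(list(stage = stage, nodes = sort(unique(as.character(nodes))),
                 edges = edges, r_th = r_th, weighted = weighted),
            class = "stage_network")
}

#' @export
print.stage_network <- function(x, ...) {
  cat("stage_network:", if (is.na(x$stage)) "<no stage>" else x$stage,
      "|", length(x$nodes), "nodes,", nrow(x$edges), "edges",
      "| r_th =", format(x$r_th, digits = 4),
      "|", if (x$weighted) "weighted" else "unweighted", "\n")
  invisible(x)
}

edge_keys <- function(network) {
  paste(network$edges$gene_a, network$edges$gene_b, sep = "\r")
}

#' Critical Pearson correlation for a given sample size
#'
#' Inverts the two-sided Pearson correlation test: returns the r >= 0 whose
#' test statistic t = r * sqrt(df) / sqrt(1 - r^2), with df = n - 2, has
#' two-sided p-value exactly `p`. Strictly decreasing in `n_samples`.
#'
#' @param n_samples Number of samples (>= 3).
#' @param p Two-sided p-value threshold in (0, 1] (default 0.001).
#' @return The critical correlation magnitude.
#' @export
critical_r <- function(n_samples, p = 0.001) {
  if (any(n_samples < 3L)) stop("n_samples must be at least 3")
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]")
  df <- n_samples - 2
  tc <- qt(1 - p / 2, df)
  tc / sqrt(df + tc^2)
}

#' Build a stage-specific correlation network
#'
#' Computes all pairwise Pearson correlations over the supplied (gene-level)
#' matrix and keeps pairs with |r| >= the critical correlation for the stage's
#' sample count at threshold `p`. Weighted networks carry |r| as edge weight;
#' unweighted networks carry 1. Genes constant across the stage's samples are
#' excluded with a warning. Correlations are computed in row blocks so the
#' full d x d matrix is never materialized.
#'
#' @param matrix Gene-level expression matrix restricted to one stage's
#'   samples (and typically to the master DEG list); >= 2 genes, >= 3 samples.
#' @param p Edge p-value threshold (default 0.001).
#' @param weighted Logical (default TRUE).
#' @param stage Stage label stored on the network.
#' @param block_size Number of genes per correlation block (default 512).
#' @return A [stage_network()].
#' @export
build_stage_network <- function(matrix, p = 0.001, weighted = TRUE,
                                stage = NA_character_, block_size = 512L) {
  n <- ncol(matrix)
  if (n < 3L) stop("network construction needs at least 3 samples")
  if (nrow(matrix) < 2L) stop("network construction needs at least 2 genes")
  ctr <- matrix - rowMeans(matrix)
  ss <- rowSums(ctr^2)
  keep <- ss > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance gene(s) dropped from stage '",
            stage, "' network")
  ctr <- ctr[keep, , drop = FALSE]
  Z <- ctr / sqrt(ss[keep])
  d <- nrow(Z)
  genes <- rownames(Z)
  r_th <- critical_r(n, p)
  starts <- seq(1L, d, by = block_size)
  ia <- list(); ib <- list(); iw <- list(); nb <- 0L
  for (bi in seq_along(starts)) {
    ri <- starts[bi]:min(starts[bi] + block_size - 1L, d)
    for (bj in bi:length(starts)) {
      rj <- starts[bj]:min(starts[bj] + block_size - 1L, d)
      C <- Z[ri, , drop = FALSE] %*% t(Z[rj, , drop = FALSE])
      hit <- abs(C) >= r_th
      if (bi == bj) hit[lower.tri(hit, diag = TRUE)] <- FALSE
      idx <- which(hit, arr.ind = TRUE)
      if (nrow(idx)) {
        nb <- nb + 1L
        ia[[nb]] <- ri[idx[, 1L]]
        ib[[nb]] <- rj[idx[, 2L]]
        iw[[nb]] <- pmin(abs(C[idx]), 1)
      }
    }
  }
  if (nb) {
    edges <- data.frame(gene_a = genes[unlist(ia)], gene_b = genes[unlist(ib)],
                        weight = if (weighted) unlist(iw) else 1,
                        stringsAsFactors = FALSE)
  } else edges <- NULL
  stage_network(edges, nodes = genes, stage = stage, r_th = r_th,
                weighted = weighted)
}

#' Stage-unique network
#'
#' Removes from `target` every edge (as an unordered pair, weights ignored for
#' membership) present in any of the `others`; surviving edges keep their
#' weights from `target`.
#'
#' @param target A [stage_network()].
#' @param others List of [stage_network()]s to subtract.
#' @return A [stage_network()] with the same nodes and metadata as `target`.
#' @export
stage_unique_network <- function(target, others) {
  other_keys <- unique(unlist(lapply(others, edge_keys)))
  keep <- !edge_keys(target) %in% other_keys
  stage_network(target$edges[keep, , drop = FALSE], nodes = target$nodes,
                stage = target$stage, r_th = target$r_th,
                weighted = target$weighted)
}

#' Per-gene weights: sum of incident edge weights
#'
#' @param network A weighted [stage_network()].
#' @return Named numeric vector over all network nodes; isolated nodes get 0.
#' @export
gene_weights <- function(network) {
  w <- setNames(numeric(length(network$nodes)), network$nodes)
  if (nrow(network$edges)) {
    wa <- tapply(network$edges$weight, network$edges$gene_a, sum)
    wb <- tapply(network$edges$weight, network$edges$gene_b, sum)
    w[names(wa)] <- w[names(wa)] + wa
    w[names(wb)] <- w[names(wb)] + wb
  }
  w
}

#' Extract a supervised key-gene subnetwork
#'
#' For each key gene, its PPI partners with score >= `score_min` are ranked by
#' score (ties broken lexicographically by partner id) and truncated to the
#' top `max_neighbors`. The node set is (key genes plus their retained
#' neighbors) intersected with the master DEG list; the result is the induced
#' subgraph of `stage_net` on that node set, preserving |PCC| edge weights.
#'
#' @param key_genes Non-empty character vector.
#' @param ppi Scored edge list from [read_edges()].
#' @param master Character vector: master DEG list.
#' @param stage_net A [stage_network()].
#' @param score_min Minimum PPI score (default 0.4).
#' @param max_neighbors Per-key-gene neighbor cap (default 20).
#' @return A [stage_network()].
#' @export
extract_key_subnetwork <- function(key_genes, ppi, master, stage_net,
                                   score_min = 0.4, max_neighbors = 20L) {
  if (!length(key_genes)) stop("key_genes must be non-empty")
  neighbors <- unlist(lapply(key_genes, function(k) {
    inc <- ppi[ppi$gene_a == k | ppi$gene_b == k, , drop = FALSE]
    inc <- inc[inc$score >= score_min, , drop = FALSE]
    partner <- ifelse(inc$gene_a == k, inc$gene_b, inc$gene_a)
    ord <- order(-inc$score, partner)
    partner[ord][seq_len(min(max_neighbors, length(ord)))]
  }))
  nodes <- intersect(sort(unique(c(key_genes, neighbors))), master)
  keep <- stage_net$edges$gene_a %in% nodes & stage_net$edges$gene_b %in% nodes
  stage_network(stage_net$edges[keep, , drop = FALSE], nodes = nodes,
                stage = stage_net$stage, r_th = stage_net$r_th,
                weighted = stage_net$weighted)
}

#' Convert a stage network to an igraph graph
#'
#' @param network A [stage_network()].
#' @param node_attrs Optional data frame of node attributes with a `gene`
#'   column (e.g. per-stage log2fc).
#' @return An igraph object with `stage` and `r_th` graph attributes.
#' @export
as_igraph <- function(network, node_attrs = NULL) {
  vert <- data.frame(name = network$nodes, stringsAsFactors = FALSE)
  if (!is.null(node_attrs)) {
    m <- match(vert$name, node_attrs$gene)
    for (col in setdiff(colnames(node_attrs), "gene"))
      vert[[col]] <- node_attrs[[col]][m]
  }
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = vert)
  g <- igraph::set_graph_attr(g, "stage", as.character(network$stage))
  g <- igraph::set_graph_attr(g, "r_th", network$r_th)
  g
}

#' Write a network as a TSV edge list
#' @param network A [stage_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a network as GraphML
#' @inheritParams as_igraph
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path, node_attrs = NULL) {
  igraph::write_graph(as_igraph(network, node_attrs), path,
                      format = "graphml")
  invisible(path)
}
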