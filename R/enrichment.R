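#' Build an edge-based enrichment query
#'
#' Fixes the hypergeometric population at the gene-pair level: for a master
#' list of `d` genes there are `N = d(d-1)/2` possible edges, of which
#' `m_set = d_set(d_set-1)/2` lie within the gene set; a network drawing `n`
#' of the `N` possible edges is observed to contain `k` within-set edges.
#'
#' @param d Master-list gene count.
#' @param d_set Number of the set's genes present in the master list.
#' @param n Observed network edge count.
#' @param k Observed edges with both endpoints in the set.
#' @return List with `d`, `d_set`, `N`, `m_set`, `n`, `k` (validated).
#' @export
enrichment_query <- function(d, d_set, n, k) {
  N <- d * (d - 1) / 2
  m_set <- d_set * (d_set - 1) / 2
  if (d_set > d) stop("d_set cannot exceed d")
  if (n > N) stop("n cannot exceed N = d(d-1)/2")
  if (k > min(n, m_set)) stop("k cannot exceed min(n, m_set)")
  if (any(c(d, d_set, n, k) < 0)) stop("counts must be non-negative")
  list(d = d, d_set = d_set, N = N, m_set = m_set, n = n, k = k)
}

#' Edge-based hypergeometric enrichment p-value
#'
#' Upper-tail probability of observing `k` or more within-set edges when `n`
#' edges are drawn uniformly from the `N = d(d-1)/2` possible gene pairs, of
#' which `m_set` lie within the set: `phyper(k - 1, m_set, N - m_set, n,
#' lower.tail = FALSE)`. Equals 1 when `k = 0` and is non-increasing in `k`.
#'
#' @param query A list from [enrichment_query()], or `d` as a scalar when the
#'   remaining arguments are supplied.
#' @param d_set,n,k See [enrichment_query()].
#' @return The p-value in (0, 1].
#' @export
edge_enrichment_pvalue <- function(query, d_set = NULL, n = NULL, k = NULL) {
  if (!is.list(query)) query <- enrichment_query(query, d_set, n, k)
  phyper(query$k - 1, query$m_set, query$N - query$m_set, query$n,
         lower.tail = FALSE)
}

#' Count a gene set's presence and internal edges in a network
#'
#' @param network A [stage_network()].
#' @param gene_set Character vector of gene ids.
#' @param master Character vector: master DEG list.
#' @return List with `d_set` (= size of `gene_set` intersected with `master`)
#'   and `k` (= network edges with both endpoints in that intersection).
#' @export
count_set_edges <- function(network, gene_set, master) {
  inset <- intersect(gene_set, master)
  k <- sum(network$edges$gene_a %in% inset & network$edges$gene_b %in% inset)
  list(d_set = length(inset), k = k)
}

#' Edge-based enrichment of gene sets across networks
#'
#' One row per (network, set) pair with the edge-based hypergeometric p-value,
#' BH q-values within each network, and a significance flag at `alpha`.
#'
#' @param networks Named list of [stage_network()]s.
#' @param sets Named list of gene sets (from [read_gmt()]).
#' @param master Character vector: master DEG list.
#' @param alpha Significance cut-off on the raw p-value (default 0.05).
#' @return Data frame with columns `network`, `set`, `d_set`, `k`, `p_value`,
#'   `q_value`, `significant`, sorted by network then p-value.
#' @export
enrich_networks <- function(networks, sets, master, alpha = 0.05) {
  if (is.null(names(networks)))
    names(networks) <- vapply(networks, function(x) as.character(x$stage), "")
  d <- length(master)
  out <- do.call(rbind, lapply(names(networks), function(nw) {
    net <- networks[[nw]]
    n <- nrow(net$edges)
    rows <- do.call(rbind, lapply(names(sets), function(s) {
      cnt <- count_set_edges(net, sets[[s]], master)
      p <- edge_enrichment_pvalue(enrichment_query(d, cnt$d_set, n, cnt$k))
      data.frame(network = nw, set = s, d_set = cnt$d_set, k = cnt$k,
                 p_value = p, stringsAsFactors = FALSE)
    }))
    rows$q_value <- p.adjust(rows$p_value, method = "BH")
    rows[order(rows$p_value, rows$set), , drop = FALSE]
  }))
  out$significant <- out$p_value <= alpha
  rownames(out) <- NULL
  out
}

#' Gene-based (node) hypergeometric enrichment
#'
#' Secondary utility applying the same machinery at the node level: population
#' `N = d` master genes, `m = d_set` set genes, draws `n` = network nodes in
#' the master list, successes `k` = set genes among them. A desk-scale stand-in
#' for web-service pathway enrichment, not a reproduction of DAVID's EASE
#' score.
#'
#' @inheritParams enrich_networks
#' @return Data frame with columns `network`, `set`, `d_set`, `k`, `p_value`,
#'   `q_value`, `significant`.
#' @export
enrich_genes <- function(networks, sets, master, alpha = 0.05) {
  if (is.null(names(networks)))
    names(networks) <- vapply(networks, function(x) as.character(x$stage), "")
  d <- length(master)
  out <- do.call(rbind, lapply(names(networks), function(nw) {
    nodes <- intersect(networks[[nw]]$nodes, master)
    rows <- do.call(rbind, lapply(names(sets), function(s) {
      inset <- intersect(sets[[s]], master)
      k <- length(intersect(nodes, inset))
      p <- phyper(k - 1, length(inset), d - length(inset), length(nodes),
                  lower.tail = FALSE)
      data.frame(network = nw, set = s, d_set = length(inset), k = k,
                 p_value = p, stringsAsFactors = FALSE)
    }))
    rows$q_value <- p.adjust(rows$p_value, method = "BH")
    rows[order(rows$p_value, rows$set), , drop = FALSE]
  }))
  out$significant <- out$p_value <= alpha
  rownames(out) <- NULL
  out
}
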