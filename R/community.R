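#' Construct a partition object
#'
#' @param membership Named integer vector: node id -> community id (dense
#'   integers from 0).
#' @param modularity Modularity Q of the partition on its network (may be NA
#'   when the partition is not tied to a network).
#' @return Object of class `partition`.
#' @export
partition <- function(membership, modularity = NA_real_) {
  m <- as.integer(membership)
  names(m) <- names(membership)
  if (is.null(names(m)) || any(!nzchar(names(m))))
    stop("membership must be a named vector")
  u <- sort(unique(m))
  if (length(u) && !identical(u, seq_along(u) - 1L))
    m <- setNames(match(m, u) - 1L, names(m))
  structure(list(membership = m, modularity = modularity),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("partition:", length(x$membership), "nodes,",
      length(unique(x$membership)), "communities, Q =",
      format(x$modularity, digits = 4), "\n")
  invisible(x)
}

as_membership <- function(x) {
  if (inherits(x, "partition")) x$membership else x
}

#' Newman modularity of a partition
#'
#' Q = sum over communities of `W_c / W - (S_c / 2W)^2`, with W the total edge
#' weight, W_c the intra-community weight and S_c the community's total
#' weighted degree. For unweighted networks every weight is 1.
#'
#' @param network A [stage_network()] with at least one edge.
#' @param partition A [partition()] or named membership vector covering every
#'   edge endpoint.
#' @return Modularity Q in \[-0.5, 1\].
#' @export
modularity <- function(network, partition) {
  m <- as_membership(partition)
  e <- network$edges
  if (!nrow(e)) stop("modularity is undefined on an empty edge set")
  ca <- m[e$gene_a]
  cb <- m[e$gene_b]
  if (anyNA(ca) || anyNA(cb))
    stop("partition does not cover every edge endpoint")
  W <- sum(e$weight)
  intra <- sum(e$weight[ca == cb])
  deg <- gene_weights(network)
  mm <- m[names(m) %in% names(deg)]
  S <- tapply(deg[names(mm)], mm, sum)
  intra / W - sum((S / (2 * W))^2)
}

#' Louvain community detection
#'
#' Two-phase modularity maximization: local node moves (sweep order shuffled
#' by `seed`, ties in modularity gain broken by the lowest candidate community
#' id) followed by community aggregation, iterated until the modularity gain
#' of a level falls below `tol`. Operates on the edge-bearing subgraph;
#' isolated nodes are excluded from the partition. The returned Q is
#' recomputed independently with [modularity()].
#'
#' @param network A [stage_network()] with at least one edge.
#' @param seed Integer seed controlling the node sweep order.
#' @param tol Minimum per-level modularity gain (default 1e-7).
#' @return A [partition()] over the edge-bearing nodes.
#' @export
louvain <- function(network, seed = 1L, tol = 1e-7) {
  e <- network$edges
  if (!nrow(e)) stop("Louvain requires at least one edge")
  nodes <- sort(unique(c(e$gene_a, e$gene_b)))
  ia <- match(e$gene_a, nodes) - 1L
  ib <- match(e$gene_b, nodes) - 1L
  comm <- cpp_louvain(ia, ib, as.numeric(e$weight), length(nodes),
                      as.integer(seed), tol)
  p <- partition(setNames(comm, nodes))
  p$modularity <- modularity(network, p)
  p
}

canonical_labels <- function(m) {
  # relabel communities by first appearance in node-name order
  m <- m[order(names(m))]
  match(m, unique(m))
}

#' Normalized mutual information between two partitions
#'
#' Contingency-table NMI with sum-of-entropies normalization
#' (`2 I(A, B) / (H(A) + H(B))`, natural logs). Identical partitions give 1.
#' If either partition has a single community (zero entropy) and the two are
#' not identical, the value is 0 by convention.
#'
#' @param a,b [partition()]s or named membership vectors over the same node
#'   set.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(a, b) {
  ma <- as_membership(a)
  mb <- as_membership(b)
  if (!setequal(names(ma), names(mb)))
    stop("partitions must cover the same node set")
  nodes <- sort(names(ma))
  ca <- canonical_labels(ma)
  cb <- canonical_labels(mb)
  if (identical(ca, cb)) return(1)
  tab <- table(ma[nodes], mb[nodes])
  N <- sum(tab)
  ni <- rowSums(tab)
  nj <- colSums(tab)
  Ha <- -sum(ni / N * log(ni / N))
  Hb <- -sum(nj / N * log(nj / N))
  if (Ha == 0 || Hb == 0) return(0)
  nz <- tab > 0
  MI <- sum(tab[nz] / N * log(tab[nz] * N / outer(ni, nj)[nz]))
  max(0, min(1, 2 * MI / (Ha + Hb)))
}

#' Jaccard index matrix between the communities of two partitions
#'
#' Entry (i, j) is `|C_i intersect D_j| / |C_i union D_j|` for community i of
#' `a` and community j of `b`; the partitions may cover different gene sets.
#'
#' @param a,b [partition()]s or named membership vectors.
#' @return Numeric matrix, rows = communities of `a`, columns = of `b`.
#' @export
jaccard_matrix <- function(a, b) {
  ma <- as_membership(a)
  mb <- as_membership(b)
  ca <- split(names(ma), ma)
  cb <- split(names(mb), mb)
  out <- matrix(0, length(ca), length(cb),
                dimnames = list(names(ca), names(cb)))
  for (i in seq_along(ca)) for (j in seq_along(cb))
    out[i, j] <- length(intersect(ca[[i]], cb[[j]])) /
      length(union(ca[[i]], cb[[j]]))
  out
}

#' Degree-preserving randomization by double-edge swaps
#'
#' Attempts `n_swaps` swaps: two edges (a,b), (c,d) are rewired to (a,d),
#' (c,b) unless that would create a self-loop or duplicate edge. Node count,
#' edge count and the degree multiset are exactly preserved; weights travel
#' with the rewired edge slots. Deterministic given `seed`.
#'
#' @param network A [stage_network()] with >= 2 edges (fewer are returned
#'   unchanged).
#' @param n_swaps Number of attempted swaps (default `10 * edge count`).
#' @param seed Integer seed.
#' @return A [stage_network()] with the same nodes and metadata.
#' @export
degree_preserving_randomize <- function(network,
                                        n_swaps = 10L * nrow(network$edges),
                                        seed = 1L) {
  e <- network$edges
  if (nrow(e) < 2L) return(network)
  nodes <- network$nodes
  ia <- match(e$gene_a, nodes) - 1L
  ib <- match(e$gene_b, nodes) - 1L
  sw <- cpp_edge_swap(ia, ib, length(nodes), as.integer(n_swaps),
                      as.integer(seed))
  stage_network(data.frame(gene_a = nodes[sw$a + 1L],
                           gene_b = nodes[sw$b + 1L],
                           weight = e$weight, stringsAsFactors = FALSE),
                nodes = nodes, stage = network$stage, r_th = network$r_th,
                weighted = network$weighted)
}

#' NMI between the Louvain partitions of two networks
#'
#' Communities are detected on each network's edge-bearing subgraph and NMI is
#' computed on the intersection of the two edge-bearing node sets (nodes
#' outside the intersection are dropped).
#'
#' @param net_a,net_b [stage_network()]s sharing at least two nodes.
#' @param seed_a,seed_b Seeds for the two Louvain runs.
#' @return NMI value in \[0, 1\].
#' @export
network_nmi <- function(net_a, net_b, seed_a = 1L, seed_b = 2L) {
  pa <- louvain(net_a, seed_a)$membership
  pb <- louvain(net_b, seed_b)$membership
  common <- intersect(names(pa), names(pb))
  if (length(common) < 2L)
    stop("networks share fewer than 2 edge-bearing nodes")
  nmi(pa[common], pb[common])
}

#' Permutation test for the NMI between two networks' communities
#'
#' The observed statistic is [network_nmi()] on the two networks. Under the
#' null, both networks are independently degree-preservingly randomized,
#' communities are re-detected and NMI recorded, `n_perm` times. The upper
#' tail p-value uses the add-one estimator
#' `(1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param net_a,net_b [stage_network()]s.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; all sub-seeds are derived from it.
#' @return List with `observed_nmi`, `null_nmis`, `p_value`, `n_perm`, `seed`.
#' @export
nmi_permutation_test <- function(net_a, net_b, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  set.seed(seed)
  subs <- sample.int(.Machine$integer.max, 2L + 4L * n_perm)
  observed <- network_nmi(net_a, net_b, subs[1L], subs[2L])
  null_nmis <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    o <- 2L + 4L * (i - 1L)
    ra <- degree_preserving_randomize(net_a, seed = subs[o + 1L])
    rb <- degree_preserving_randomize(net_b, seed = subs[o + 2L])
    null_nmis[i] <- network_nmi(ra, rb, subs[o + 3L], subs[o + 4L])
  }
  list(observed_nmi = observed, null_nmis = null_nmis,
       p_value = (1 + sum(null_nmis >= observed)) / (1 + n_perm),
       n_perm = n_perm, seed = seed)
}

#' Pairwise NMI matrix across a list of networks
#'
#' @param networks Named list of [stage_network()]s.
#' @param seed Base seed for the Louvain runs.
#' @return Symmetric matrix of pairwise [network_nmi()] values with unit
#'   diagonal.
#' @export
nmi_matrix <- function(networks, seed = 1L) {
  k <- length(networks)
  out <- matrix(1, k, k, dimnames = list(names(networks), names(networks)))
  parts <- lapply(seq_len(k), function(i)
    louvain(networks[[i]], seed + i)$membership)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    common <- intersect(names(parts[[i]]), names(parts[[j]]))
    out[i, j] <- out[j, i] <-
      if (length(common) >= 2L) nmi(parts[[i]][common], parts[[j]][common])
      else NA_real_
  }
  out
}

#' Write a partition to TSV
#' @param p A [partition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(p, path) {
  write.table(data.frame(gene = names(p$membership),
                         community = unname(p$membership)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
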