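# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Hypergeometric upper tail P[X >= k] by direct summation of exact
# choose() products (exact integers in doubles up to N = 28).
enum_hyper_tail <- function(N, m, n, k) {
  lo <- max(k, n - (N - m))
  hi <- min(m, n)
  if (lo > hi) return(if (k <= 0) 1 else 0)
  if (k <= max(0, n - (N - m))) return(1)
  sum(vapply(lo:hi, function(i) choose(m, i) * choose(N - m, n - i),
             numeric(1L))) / choose(N, n)
}

# Same tail by literal enumeration of all n-edge subsets of the N possible
# edges (feasible only for small choose(N, n)).
enum_hyper_subsets <- function(N, m, n, k) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= m)  # edges 1..m are the within-set edges
  mean(hits >= k)
}

# All set partitions of n items as restricted growth strings (rows).
all_partitions <- function(n) {
  P <- matrix(0L, 1L, 1L)
  maxl <- 0L
  for (i in seq_len(n - 1L)) {
    reps <- maxl + 2L
    idx <- rep(seq_len(nrow(P)), reps)
    newlab <- unlist(lapply(seq_len(nrow(P)), function(r) 0:(maxl[r] + 1L)))
    P <- cbind(P[idx, , drop = FALSE], newlab, deparse.level = 0L)
    maxl <- pmax(maxl[idx], newlab)
  }
  P
}

# Exhaustive modularity maximum over every partition of the network's nodes.
# Vectorized over the partition matrix; returns the optimum Q and one argmax.
max_modularity_exhaustive <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  e <- net$edges
  ea <- match(e$gene_a, nodes)
  eb <- match(e$gene_b, nodes)
  w <- e$weight
  W <- sum(w)
  deg <- numeric(n)
  for (i in seq_along(w)) {
    deg[ea[i]] <- deg[ea[i]] + w[i]
    deg[eb[i]] <- deg[eb[i]] + w[i]
  }
  P <- all_partitions(n)
  intra <- (P[, ea, drop = FALSE] == P[, eb, drop = FALSE]) %*% w
  ssq <- numeric(nrow(P))
  for (lab in 0:(n - 1L)) {
    S <- (P == lab) %*% deg
    ssq <- ssq + (S / (2 * W))^2
  }
  Q <- as.numeric(intra / W - ssq)
  best <- which.max(Q)
  list(Q = Q[best], membership = setNames(P[best, ], nodes))
}

# NMI oracle: igraph's implementation (Danon sum-of-entropies).
igraph_nmi <- function(a, b) {
  nodes <- sort(names(a))
  igraph::compare(as.integer(factor(a[nodes])),
                  as.integer(factor(b[nodes])), method = "nmi")
}
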