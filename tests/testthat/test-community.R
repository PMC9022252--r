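test_that("modularity matches direct evaluation of the formula", {
  tri <- function(a, b, c) unit_edges(c(a, a, b), c(b, c, c))
  net <- stage_network(rbind(tri("a", "b", "c"), tri("d", "e", "f")))
  two <- setNames(c(0, 0, 0, 1, 1, 1), c("a", "b", "c", "d", "e", "f"))
  expect_equal(modularity(net, two), 0.5)
  one <- setNames(rep(0L, 6), c("a", "b", "c", "d", "e", "f"))
  expect_equal(modularity(net, one), 0)
  edge <- stage_network(unit_edges("a", "b"))
  expect_equal(modularity(edge, setNames(0:1, c("a", "b"))), -0.5)
  empty <- stage_network(NULL, nodes = c("a", "b"))
  expect_error(modularity(empty, one), "empty edge set")
  # weighted case against igraph
  set.seed(20)
  net2 <- gnp_network(15L, 0.3, 21L)
  net2$edges$weight <- runif(nrow(net2$edges), 0.4, 1)
  m <- setNames(sample(0:2, 15, replace = TRUE), net2$nodes)
  g <- igraph::graph_from_data_frame(net2$edges, directed = FALSE,
                                     vertices = net2$nodes)
  ref <- igraph::modularity(g, membership = m[igraph::V(g)$name] + 1L,
                            weights = igraph::E(g)$weight)
  expect_equal(modularity(net2, m), ref, tolerance = 1e-12)
})

test_that("louvain recovers planted structure on canonical fixtures", {
  net <- two_cliques_bridge()
  p <- louvain(net, seed = 3L)
  split_found <- split(names(p$membership), p$membership)
  expect_setequal(vapply(split_found, function(s)
    paste(sort(s), collapse = ","), ""),
    c(paste(sprintf("a%02d", 1:5), collapse = ","),
      paste(sprintf("b%02d", 1:5), collapse = ",")))
  # equality with the exhaustive optimum
  ex <- max_modularity_exhaustive(net)
  expect_equal(p$modularity, ex$Q, tolerance = 1e-12)
  # complete graph: a single community (every split lowers Q)
  k6 <- stage_network(clique_edges(sprintf("k%d", 1:6)))
  p6 <- louvain(k6, seed = 1L)
  expect_identical(length(unique(p6$membership)), 1L)
  expect_equal(max_modularity_exhaustive(k6)$Q, 0)
  # returned Q equals an independent recomputation
  expect_equal(p$modularity, modularity(net, p), tolerance = 1e-15)
  expect_error(louvain(stage_network(NULL, nodes = "a")), "at least one edge")
})

test_that("louvain never spans disconnected components or drops below singletons", {
  net <- stage_network(rbind(clique_edges(c("a1", "a2", "a3")),
                             clique_edges(c("b1", "b2", "b3"))))
  p <- louvain(net, seed = 7L)
  comp_of <- substr(names(p$membership), 1, 1)
  expect_true(all(tapply(comp_of, p$membership,
                         function(x) length(unique(x))) == 1L))
  for (seed in 1:5) {
    g <- gnp_network(20L, 0.15, 100L + seed)
    if (!nrow(g$edges)) next
    p <- louvain(g, seed = seed)
    nodes <- sort(unique(c(g$edges$gene_a, g$edges$gene_b)))
    singletons <- setNames(seq_along(nodes) - 1L, nodes)
    expect_gte(p$modularity, modularity(g, singletons) - 1e-12)
  }
})

test_that("louvain stays within the exhaustive optimum on small graphs", {
  for (seed in 1:6) {
    g <- gnp_network(8L, 0.35, 200L + seed)
    if (nrow(g$edges) < 2L) next
    ex <- max_modularity_exhaustive(g)
    best <- max(vapply(1:5, function(s) louvain(g, seed = s)$modularity,
                       numeric(1L)))
    expect_lte(best, ex$Q + 1e-12)
  }
})

test_that("nmi follows the sum-of-entropies definition and conventions", {
  a <- setNames(c(0, 0, 1, 1), c("a", "b", "c", "d"))
  b <- setNames(c(0, 1, 0, 1), c("a", "b", "c", "d"))
  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(a, b), 0)  # independent tables
  expect_equal(nmi(a, setNames(rep(0, 4), names(a))), 0)  # zero entropy
  expect_equal(nmi(setNames(rep(0, 4), names(a)),
                   setNames(rep(5, 4), names(a))), 1)  # identical grouping
  expect_error(nmi(a, b[1:3]), "same node set")
  # symmetry, relabel invariance, igraph agreement
  set.seed(30)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    nodes <- sprintf("n%03d", seq_len(n))
    x <- setNames(sample(0:4, n, replace = TRUE), nodes)
    y <- setNames(sample(0:3, n, replace = TRUE), nodes)
    v <- nmi(x, y)
    expect_equal(v, nmi(y, x), tolerance = 1e-14)
    relab <- setNames(9L - x, nodes)
    expect_equal(nmi(relab, y), v, tolerance = 1e-14)
    expect_equal(v, igraph_nmi(x, y), tolerance = 1e-12)
  }
})

test_that("jaccard matrix compares community gene sets", {
  a <- setNames(c(0, 0, 0, 1), c("a", "b", "c", "x"))
  b <- setNames(c(0, 0, 0, 1), c("b", "c", "d", "y"))
  J <- jaccard_matrix(a, b)
  expect_equal(J["0", "0"], 0.5)  # {a,b,c} vs {b,c,d}
  expect_equal(J["1", "1"], 0)    # disjoint
  expect_equal(jaccard_matrix(a, a)["0", "0"], 1)
})

test_that("degree-preserving randomization keeps the degree multiset", {
  deg_multiset <- function(net) {
    d <- table(c(net$edges$gene_a, net$edges$gene_b))
    sort(as.integer(d))
  }
  for (seed in 1:10) {
    g <- gnp_network(20L, 0.2, 300L + seed)
    r <- degree_preserving_randomize(g, seed = seed)
    expect_identical(deg_multiset(r), deg_multiset(g))
    expect_identical(nrow(r$edges), nrow(g$edges))
    expect_identical(r$nodes, g$nodes)
  }
  # same seed, same output
  g <- gnp_network(25L, 0.2, 314L)
  expect_identical(degree_preserving_randomize(g, seed = 9L)$edges,
                   degree_preserving_randomize(g, seed = 9L)$edges)
  # a graph with >= 20 edges actually gets rewired
  expect_gte(nrow(g$edges), 20L)
  r <- degree_preserving_randomize(g, seed = 9L)
  expect_false(identical(r$edges[, 1:2], g$edges[, 1:2]))
  # star K1,3: no valid swap exists, graph returned unchanged
  star <- stage_network(unit_edges(rep("hub", 3), c("l1", "l2", "l3")))
  expect_identical(degree_preserving_randomize(star, seed = 1L)$edges,
                   star$edges)
})

test_that("nmi permutation test uses the add-one upper-tail estimator", {
  # strong shared structure: observed NMI should beat a randomized null
  net_a <- stage_network(rbind(clique_edges(sprintf("a%d", 1:6)),
                               clique_edges(sprintf("b%d", 1:6)),
                               clique_edges(sprintf("c%d", 1:6)),
                               unit_edges(c("a1", "b1"), c("b1", "c1"))))
  res <- nmi_permutation_test(net_a, net_a, n_perm = 49L, seed = 5L)
  expect_length(res$null_nmis, 49L)
  expect_identical(res$p_value,
                   (1 + sum(res$null_nmis >= res$observed_nmi)) / 50)
  expect_equal(res$observed_nmi, 1)
  expect_lte(res$p_value, 0.1)
  res2 <- nmi_permutation_test(net_a, net_a, n_perm = 49L, seed = 5L)
  expect_identical(res2$null_nmis, res$null_nmis)  # seeded determinism
  expect_error(nmi_permutation_test(net_a, net_a, n_perm = 0L), "at least 1")
})

test_that("the nmi matrix has unit diagonal and symmetric entries", {
  nets <- list(I = gnp_network(20L, 0.25, 41L),
               II = gnp_network(20L, 0.25, 42L),
               III = gnp_network(20L, 0.25, 43L))
  M <- nmi_matrix(nets, seed = 2L)
  expect_equal(unname(diag(M)), rep(1, 3))
  expect_equal(M, t(M))
  expect_true(all(M >= 0 & M <= 1))
})
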