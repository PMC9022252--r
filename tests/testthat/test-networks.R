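test_that("critical_r inverts the two-sided correlation test", {
  expect_equal(critical_r(10, 1), 0)
  # strictly decreasing in n
  rs <- critical_r(3:50)
  expect_true(all(diff(rs) < 0))
  # independent numeric inversion of the t survival function by bisection
  bisect_r <- function(n, p) {
    f <- function(r) {
      t <- r * sqrt(n - 2) / sqrt(1 - r^2)
      2 * pt(t, n - 2, lower.tail = FALSE) - p
    }
    lo <- 0; hi <- 1 - 1e-12
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (n in c(5, 13, 37)) {
    expect_equal(critical_r(n, 0.001), bisect_r(n, 0.001), tolerance = 1e-10)
    expect_equal(critical_r(n, 0.05), bisect_r(n, 0.05), tolerance = 1e-10)
  }
  # round trip: the returned r has exactly the requested p-value
  r <- critical_r(20, 0.001)
  t <- r * sqrt(18) / sqrt(1 - r^2)
  expect_equal(2 * pt(-t, 18), 0.001, tolerance = 1e-12)
  expect_error(critical_r(2), "at least 3")
})

test_that("perfectly dependent gene pairs become unit-weight edges", {
  x <- c(1, 2, 3, 4, 5)
  m <- rbind(g1 = x, g2 = 2 * x, g3 = -x + 10)
  colnames(m) <- sprintf("s%d", 1:5)
  net <- build_stage_network(m, p = 0.001, stage = "I")
  expect_identical(nrow(net$edges), 3L)  # all pairs |r| = 1
  expect_equal(net$edges$weight, rep(1, 3))
  un <- build_stage_network(m, p = 0.001, weighted = FALSE)
  expect_equal(un$edges$weight, rep(1, 3))
  expect_identical(nrow(un$edges), nrow(net$edges))
})

test_that("independent pairs form edges at about the nominal rate", {
  set.seed(10)
  n <- 37L
  a <- matrix(rnorm(10000 * n), 10000, n)
  b <- matrix(rnorm(10000 * n), 10000, n)
  za <- (a - rowMeans(a)) / sqrt(rowSums((a - rowMeans(a))^2))
  zb <- (b - rowMeans(b)) / sqrt(rowSums((b - rowMeans(b))^2))
  r <- rowSums(za * zb)
  hits <- sum(abs(r) >= critical_r(n, 0.001))
  expect_gte(hits, 1L)    # binomial(10000, 0.001)
  expect_lte(hits, 30L)
})

test_that("zero-variance genes are dropped from the stage network only", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(5, 5, 5, 5))
  colnames(m) <- sprintf("s%d", 1:4)
  expect_warning(net <- build_stage_network(m, p = 0.05), "zero-variance")
  expect_false("g3" %in% net$nodes)
  expect_error(build_stage_network(m[, 1:2]), "at least 3 samples")
})

test_that("blocked correlation agrees with the dense computation", {
  set.seed(11)
  m <- matrix(rnorm(80 * 12), 80, 12,
              dimnames = list(sprintf("g%03d", 1:80), sprintf("s%02d", 1:12)))
  dense <- build_stage_network(m, p = 0.05)
  blocked <- build_stage_network(m, p = 0.05, block_size = 7L)
  expect_identical(blocked$edges[, c("gene_a", "gene_b")],
                   dense$edges[, c("gene_a", "gene_b")])
  expect_equal(blocked$edges$weight, dense$edges$weight)
  # oracle: every retained pair is significant under cor.test
  for (i in sample(nrow(dense$edges), 5)) {
    p <- cor.test(m[dense$edges$gene_a[i], ],
                  m[dense$edges$gene_b[i], ])$p.value
    expect_lte(p, 0.05 + 1e-12)
  }
})

test_that("stage-unique networks subtract edges by pair identity", {
  target <- stage_network(unit_edges(c("a", "b"), c("b", "c")), stage = "I")
  other <- stage_network(data.frame(gene_a = c("b", "c"),
                                    gene_b = c("c", "d"),
                                    weight = c(0.4, 0.6)))
  u <- stage_unique_network(target, list(other))
  expect_identical(u$edges$gene_a, "a")
  expect_identical(u$edges$gene_b, "b")
  expect_identical(nrow(stage_unique_network(target, list(target))$edges), 0L)
  expect_identical(stage_unique_network(target, list())$edges, target$edges)
})

test_that("unique/specific edge algebra holds on random network families", {
  for (seed in 1:5) {
    nets <- lapply(1:3, function(i) gnp_network(25L, 0.15, seed * 10L + i))
    uniq <- lapply(1:3, function(i)
      stage_unique_network(nets[[i]], nets[-i]))
    for (i in 1:3) {
      ku <- paste(uniq[[i]]$edges$gene_a, uniq[[i]]$edges$gene_b)
      ks <- paste(nets[[i]]$edges$gene_a, nets[[i]]$edges$gene_b)
      expect_true(all(ku %in% ks))
      for (j in setdiff(1:3, i)) {
        kt <- paste(nets[[j]]$edges$gene_a, nets[[j]]$edges$gene_b)
        expect_length(intersect(ku, kt), 0L)
      }
    }
  }
})

test_that("gene weights sum incident |PCC| weights", {
  net <- stage_network(data.frame(gene_a = c("a", "a"), gene_b = c("b", "c"),
                                  weight = c(0.8, 0.9)),
                       nodes = c("a", "b", "c", "iso"))
  w <- gene_weights(net)
  expect_equal(w[["a"]], 1.7)
  expect_equal(w[["iso"]], 0)
  expect_equal(sum(w), 2 * sum(net$edges$weight))  # handshake identity
})

test_that("key-gene subnetworks respect score threshold and neighbor cap", {
  master <- c("K", sprintf("P%02d", 1:30), "Q")
  stage_net <- stage_network(
    data.frame(gene_a = "K", gene_b = sprintf("P%02d", 1:30), weight = 0.9),
    nodes = master)
  # 25 partners at score 0.9 -> exactly 20 retained, lexicographically first
  ppi <- data.frame(gene_a = "K", gene_b = sprintf("P%02d", 1:25),
                    score = 0.9, stringsAsFactors = FALSE)
  sub <- extract_key_subnetwork("K", ppi, master, stage_net)
  expect_identical(sub$nodes, sort(c("K", sprintf("P%02d", 1:20))))
  # partner below threshold excluded
  ppi2 <- data.frame(gene_a = "K", gene_b = c("P01", "P02"),
                     score = c(0.39, 0.41), stringsAsFactors = FALSE)
  sub2 <- extract_key_subnetwork("K", ppi2, master, stage_net)
  expect_identical(sub2$nodes, c("K", "P02"))
  # ranking prefers score over lexicographic order
  ppi3 <- data.frame(gene_a = "K", gene_b = c("P01", "P02", "P03"),
                     score = c(0.5, 0.9, 0.8), stringsAsFactors = FALSE)
  sub3 <- extract_key_subnetwork("K", ppi3, master, stage_net,
                                 max_neighbors = 2L)
  expect_identical(sub3$nodes, c("K", "P02", "P03"))
  # key gene with no partners: singleton, no edges
  sub4 <- extract_key_subnetwork("Q", ppi, master, stage_net)
  expect_identical(sub4$nodes, "Q")
  expect_identical(nrow(sub4$edges), 0L)
  expect_error(extract_key_subnetwork(character(0), ppi, master, stage_net),
               "non-empty")
})

test_that("planted blocks dominate edge density within stages", {
  ds <- small_sim(seed = 81L)
  ge <- gene_level(ds)
  sm <- stage_submatrix(ge, ds$metadata, "II")
  net <- build_stage_network(sm, stage = "II")
  bl <- ds$truth$block_membership$II
  ba <- bl[net$edges$gene_a]
  bb <- bl[net$edges$gene_b]
  within <- sum(!is.na(ba) & !is.na(bb) & ba == bb)
  size <- sum(!is.na(bl) & bl == 1L)
  n_within_pairs <- 2 * choose(size, 2)
  n_other_pairs <- choose(length(bl), 2) - n_within_pairs
  dens_within <- within / n_within_pairs
  dens_other <- (nrow(net$edges) - within) / n_other_pairs
  expect_gte(dens_within / max(dens_other, 1e-12), 10)
})

test_that("GraphML export round-trips through igraph", {
  net <- two_cliques_bridge()
  net$stage <- "II"
  net$r_th <- 0.52
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, path,
                        node_attrs = data.frame(gene = net$nodes,
                                                log2fc = seq_along(net$nodes)))
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), length(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_identical(igraph::graph_attr(g, "stage"), "II")
  expect_equal(igraph::graph_attr(g, "r_th"), 0.52)
  expect_true("log2fc" %in% igraph::vertex_attr_names(g))
})
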