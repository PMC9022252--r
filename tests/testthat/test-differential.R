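test_that("probe_test handles identical, degenerate and swapped groups", {
  x <- c(1, 2, 3, 4)
  res <- probe_test(x, x)
  expect_equal(res$p_value, 1)
  expect_equal(res$log2fc, 0)
  # exact shift with zero within-group variance: degenerate-variance rule
  expect_warning(res2 <- probe_test(c(3, 3, 3), c(1, 1, 1)), "constant")
  expect_equal(res2$log2fc, 2)
  expect_identical(res2$p_value, .Machine$double.xmin)
  res3 <- probe_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(res3$p_value, 1)
  # symmetry under group swap
  set.seed(1)
  a <- rnorm(8); b <- rnorm(12, mean = 0.6)
  f <- probe_test(a, b); g <- probe_test(b, a)
  expect_equal(f$p_value, g$p_value)
  expect_equal(f$log2fc, -g$log2fc)
  expect_error(probe_test(1, c(1, 2)), "at least 2")
})

test_that("probe_test agrees with t.test on non-degenerate data", {
  set.seed(2)
  for (i in 1:25) {
    a <- rnorm(5 + i %% 7, sd = runif(1, 0.5, 2))
    b <- rnorm(4 + i %% 5, mean = runif(1, -1, 1))
    res <- probe_test(a, b)
    ref <- t.test(a, b)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("probe-level power at the cohort's group sizes is near 1", {
  set.seed(3)
  n_sim <- 1000L
  X <- cbind(matrix(rnorm(n_sim * 13, mean = 2, sd = 0.5), n_sim, 13),
             matrix(rnorm(n_sim * 22, mean = 0, sd = 0.5), n_sim, 22))
  rownames(X) <- sprintf("g%04d", seq_len(n_sim))
  meta <- data.frame(sample_id = sprintf("s%02d", 1:35),
                     stage = rep(c("I", "normal"), c(13, 22)))
  colnames(X) <- meta$sample_id
  res <- differential_expression(X, meta, "I", "normal")
  expect_gte(mean(res$p_value <= 0.05), 0.99)
})

test_that("gene p aggregation is the geometric mean with (0,1] domain", {
  expect_identical(aggregate_gene_p(0.05), 0.05)
  expect_equal(aggregate_gene_p(c(0.01, 0.04)), 0.02)
  expect_equal(aggregate_gene_p(rep(0.3, 3)), 0.3)
  expect_error(aggregate_gene_p(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(aggregate_gene_p(numeric(0)), "empty")
  # bounded by the extremes
  set.seed(4)
  for (i in 1:50) {
    ps <- runif(sample(1:5, 1))
    agg <- aggregate_gene_p(ps)
    expect_lte(agg, max(ps))
    expect_gte(agg, min(ps))
  }
})

test_that("multi-probe genes aggregate by geometric-mean p and mean log2fc", {
  set.seed(5)
  X <- matrix(rnorm(3 * 10), 3, 10,
              dimnames = list(c("p1", "p2", "p3"), sprintf("s%02d", 1:10)))
  meta <- data.frame(sample_id = colnames(X),
                     stage = rep(c("II", "I"), each = 5))
  annot <- data.frame(probe_id = rownames(X),
                      gene_id = c("g1", "g1", "g2"),
                      stringsAsFactors = FALSE)
  probe <- differential_expression(X, meta, "II", "I")
  gene <- differential_expression(X, meta, "II", "I", annot)
  g1 <- gene[gene$gene == "g1", ]
  expect_identical(g1$n_probes, 2L)
  expect_equal(g1$p_value,
               sqrt(prod(probe$p_value[probe$gene %in% c("p1", "p2")])))
  expect_equal(g1$log2fc,
               mean(probe$log2fc[probe$gene %in% c("p1", "p2")]))
})

test_that("under the global null the p-value distribution is calibrated", {
  set.seed(6)
  X <- matrix(rnorm(10000 * 35), 10000, 35,
              dimnames = list(sprintf("g%05d", 1:10000),
                              sprintf("s%02d", 1:35)))
  meta <- data.frame(sample_id = colnames(X),
                     stage = rep(c("I", "normal"), c(13, 22)))
  res <- differential_expression(X, meta, "I", "normal")
  expect_lt(abs(mean(res$p_value <= 0.05) - 0.05), 0.01)
})

test_that("master DEG list is the union over the four comparisons", {
  fake <- function(genes, ps) data.frame(gene = genes, p_value = ps)
  res <- list(I_vs_normal = fake(c("a", "b"), c(0.01, 0.5)),
              II_vs_I = fake(c("a", "c"), c(0.9, 0.04)),
              III_vs_II = fake(c("d"), 0.2),
              IV_vs_III = fake(c("e"), 0.001))
  expect_identical(master_deg_list(res), c("a", "c", "e"))
  expect_error(master_deg_list(res[-2]), "II_vs_I")
})

test_that("planted DE structure is recovered in the master list", {
  ds <- generate_dataset(sim_config(de_effect = 3, noise_sd = 0.5,
                                    seed = 71L))  # effect/sd = 6
  probes <- drop_unmapped_probes(ds$expression, ds$annotation)
  meta <- ds$metadata[!ds$metadata$sample_id %in%
                        ds$truth$outlier_samples, ]
  probes <- probes[, meta$sample_id]
  master <- master_deg_list(neighboring_deg(probes, meta, ds$annotation))
  planted <- unique(unlist(ds$truth$de_genes))
  expect_true(all(planted %in% master))
})

test_that("stage-specific biomarkers are the four-way DEG intersection", {
  set.seed(8)
  ns <- c(normal = 8L, I = 8L, II = 8L, III = 8L, IV = 8L)
  meta <- data.frame(sample_id = sprintf("s%02d", 1:40),
                     stage = rep(names(ns), ns))
  X <- matrix(rnorm(3 * 40, sd = 0.3), 3, 40,
              dimnames = list(c("gIV", "gflat", "gI"), meta$sample_id))
  X["gIV", meta$stage == "IV"] <- X["gIV", meta$stage == "IV"] + 5
  X["gI", meta$stage == "I"] <- X["gI", meta$stage == "I"] - 5
  expect_identical(stage_specific_biomarkers(X, meta, "IV"), "gIV")
  expect_identical(stage_specific_biomarkers(X, meta, "I"), "gI")
  expect_false("gflat" %in% stage_specific_biomarkers(X, meta, "II"))
  expect_identical(stage_specific_biomarkers(X, meta, "II", alpha = 1),
                   sort(rownames(X)))
  expect_error(stage_specific_biomarkers(X, meta[meta$stage != "III", ], "IV"),
               "III")
  expect_error(stage_specific_biomarkers(X, meta, "normal"), "I, II, III, IV")
})
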