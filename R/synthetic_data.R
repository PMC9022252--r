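#' Configuration for the synthetic stage-structured expression generator
#'
#' Defaults emulate the structure of the staged colorectal-cancer microarray
#' cohort the pipeline was developed around: five stage groups with unequal
#' sample counts (22 normal, 13/37/34/20 for stages I-IV), multi-probe genes,
#' planted within-stage correlation blocks, differential expression between
#' neighboring stages (with a much larger fraction for the normal-to-stage-I
#' transition), monotone/step trend biomarker genes, and a couple of globally
#' shifted outlier samples.
#'
#' @param n_genes Number of genes (default 200).
#' @param probe_probs Probability of a gene having 1, 2 or 3 probes
#'   (default 0.4, 0.4, 0.2).
#' @param samples_per_stage Named counts for `normal, I, II, III, IV`.
#' @param n_blocks Planted correlation blocks per stage (default 4).
#' @param block_size Genes per block (default 40).
#' @param block_rho Target within-block correlation in \[0, 1) (default 0.9).
#' @param de_fraction Named per-comparison fractions of genes differentially
#'   expressed between neighboring stages.
#' @param de_effect Mean log2 shift of a DE gene (default 2).
#' @param trend_genes Named counts of planted trend biomarkers; patterns from
#'   `monotone-up`, `step-up`, `monotone-down`, `step-down`.
#' @param noise_sd Residual standard deviation (default 0.5).
#' @param n_outliers Planted outlier samples appended to the normal group
#'   (default 2).
#' @param frac_unmapped Fraction of additional junk probes with missing or
#'   multi-gene annotation (default 0.02).
#' @param seed Integer seed (default 1).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L,
                       probe_probs = c(`1` = 0.4, `2` = 0.4, `3` = 0.2),
                       samples_per_stage = c(normal = 22L, I = 13L, II = 37L,
                                             III = 34L, IV = 20L),
                       n_blocks = 4L,
                       block_size = 40L,
                       block_rho = 0.9,
                       de_fraction = c(I_vs_normal = 0.30, II_vs_I = 0.05,
                                       III_vs_II = 0.05, IV_vs_III = 0.05),
                       de_effect = 2,
                       trend_genes = c(`monotone-up` = 5L, `step-up` = 5L,
                                       `monotone-down` = 5L,
                                       `step-down` = 5L),
                       noise_sd = 0.5,
                       n_outliers = 2L,
                       frac_unmapped = 0.02,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), probe_probs = probe_probs,
              samples_per_stage = samples_per_stage,
              n_blocks = as.integer(n_blocks),
              block_size = as.integer(block_size), block_rho = block_rho,
              de_fraction = de_fraction, de_effect = de_effect,
              trend_genes = trend_genes, noise_sd = noise_sd,
              n_outliers = as.integer(n_outliers),
              frac_unmapped = frac_unmapped, seed = as.integer(seed))
  if (cfg$n_genes < 0L) stop("invalid config: n_genes must be >= 0")
  if (length(cfg$probe_probs) != 3L || any(cfg$probe_probs < 0) ||
      sum(cfg$probe_probs) <= 0)
    stop("invalid config: probe_probs must be 3 non-negative weights")
  if (!all(STAGES %in% names(cfg$samples_per_stage)))
    stop("invalid config: samples_per_stage must name all of ",
         paste(STAGES, collapse = ", "))
  if (any(cfg$samples_per_stage < 0))
    stop("invalid config: samples_per_stage counts must be >= 0")
  if (cfg$n_blocks < 0L) stop("invalid config: n_blocks must be >= 0")
  if (cfg$block_size < 0L) stop("invalid config: block_size must be >= 0")
  if (cfg$block_rho < 0 || cfg$block_rho >= 1)
    stop("invalid config: block_rho must lie in [0, 1)")
  if (any(cfg$de_fraction < 0) || any(cfg$de_fraction > 1))
    stop("invalid config: de_fraction values must lie in [0, 1]")
  bad <- setdiff(names(cfg$trend_genes),
                 c("monotone-up", "step-up", "monotone-down", "step-down"))
  if (length(bad))
    stop("invalid config: unknown trend pattern(s) in trend_genes: ",
         paste(bad, collapse = ", "))
  if (any(cfg$trend_genes < 0))
    stop("invalid config: trend_genes counts must be >= 0")
  if (cfg$noise_sd <= 0) stop("invalid config: noise_sd must be > 0")
  if (cfg$n_outliers < 0L) stop("invalid config: n_outliers must be >= 0")
  if (cfg$n_blocks * cfg$block_size + sum(cfg$trend_genes) > cfg$n_genes)
    stop("invalid config: block genes plus trend_genes exceed n_genes")
  class(cfg) <- "sim_config"
  cfg
}

trend_patterns <- list(
  `monotone-up` = c(0, 1, 2, 3, 4),
  `step-up` = c(0, 1, 1, 1, 1),
  `monotone-down` = c(0, -1, -2, -3, -4),
  `step-down` = c(0, -1, -1, -1, -1))

#' Generate a stage-structured synthetic expression dataset
#'
#' One-factor block model: within a planted block, each probe value is
#' `latent + noise_sd * sqrt(1 - rho) * eps` where the latent part shares
#' `noise_sd * sqrt(rho)` times a per-(stage, block, sample) standard normal
#' factor, so the expected pairwise probe correlation within a block is
#' exactly `block_rho`. Differential expression is planted as a persistent
#' log2 shift from the test stage onward; trend genes follow fixed
#' monotone/step patterns scaled by `de_effect`; outlier samples receive a
#' global `10 * noise_sd` shift. Multi-probe genes share the gene's latent
#' signal and differ by a fixed probe affinity plus independent probe noise.
#' Identical seeds give bit-identical output.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset` with elements `expression`
#'   (probe-level matrix), `metadata`, `annotation`, `truth` (ground-truth
#'   list), `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("G%04d", seq_len(ng))
  spst <- config$samples_per_stage[STAGES]

  # gene roles: blocks first, trend genes last, the rest free
  block_of <- rep(NA_integer_, ng)
  nb <- config$n_blocks * config$block_size
  if (nb > 0L)
    block_of[seq_len(nb)] <- rep(seq_len(config$n_blocks),
                                 each = config$block_size)
  trend_of <- rep(NA_character_, ng)
  tg <- config$trend_genes[config$trend_genes > 0]
  if (length(tg)) {
    idx <- ng - sum(tg) + seq_len(sum(tg))
    trend_of[idx] <- rep(names(tg), times = tg)
  }

  # per-stage mean offsets: trends, then neighboring-stage DE shifts
  offset <- matrix(0, ng, length(STAGES), dimnames = list(genes, STAGES))
  for (pat in names(tg)) {
    rows <- which(trend_of == pat)
    offset[rows, ] <- offset[rows, ] +
      matrix(config$de_effect * trend_patterns[[pat]], length(rows),
             length(STAGES), byrow = TRUE)
  }
  cmp_names <- names(neighboring_comparisons())
  de_genes <- list()
  eligible <- which(is.na(trend_of))
  for (i in seq_along(cmp_names)) {
    frac <- config$de_fraction[[cmp_names[i]]]
    if (is.null(frac) || is.na(frac)) frac <- 0
    n_de <- round(frac * length(eligible))
    pick <- if (n_de > 0L) sort(sample(eligible, n_de)) else integer(0L)
    de_genes[[cmp_names[i]]] <- genes[pick]
    if (length(pick)) {
      dir <- sample(c(-1, 1), length(pick), replace = TRUE)
      later <- (i + 1L):length(STAGES)  # test stage of comparison i and on
      offset[pick, later] <- offset[pick, later] +
        outer(dir * config$de_effect, rep(1, length(later)))
    }
  }

  # samples: per-stage ids plus outliers appended to the normal group
  sample_ids <- as.character(unlist(lapply(STAGES, function(s)
    sprintf("%s_%02d", s, seq_len(spst[[s]]))), use.names = FALSE))
  stage_of_sample <- rep(STAGES, times = as.integer(spst))
  if (config$n_outliers > 0L) {
    sample_ids <- c(sample_ids,
                    sprintf("normal_outlier_%02d",
                            seq_len(config$n_outliers)))
    stage_of_sample <- c(stage_of_sample, rep("normal", config$n_outliers))
  }
  ns <- length(sample_ids)

  baseline <- stats::rnorm(ng, mean = 7, sd = 1)
  rho <- config$block_rho
  sdres <- config$noise_sd * ifelse(is.na(block_of), 1, sqrt(1 - rho))

  # latent gene signal per sample (block factor shared within stage/block)
  latent <- matrix(0, ng, ns, dimnames = list(genes, sample_ids))
  for (j in seq_len(ns)) {
    s <- stage_of_sample[j]
    v <- baseline + offset[, s]
    if (config$n_blocks > 0L) {
      f <- stats::rnorm(config$n_blocks)
      bl <- !is.na(block_of)
      v[bl] <- v[bl] + config$noise_sd * sqrt(rho) * f[block_of[bl]]
    }
    latent[, j] <- v
  }
  is_outlier <- grepl("_outlier_", sample_ids, fixed = TRUE)
  latent[, is_outlier] <- latent[, is_outlier] + 10 * config$noise_sd

  # probes
  n_probes <- sample(1:3, ng, replace = TRUE,
                     prob = config$probe_probs / sum(config$probe_probs))
  probe_gene <- rep(genes, times = n_probes)
  probe_row <- rep(seq_len(ng), times = n_probes)
  probe_ids <- as.character(unlist(lapply(seq_len(ng), function(i)
    sprintf("%s_p%d", genes[i], seq_len(n_probes[i]))), use.names = FALSE))
  affinity <- stats::rnorm(length(probe_ids), 0, 0.25)
  expr <- latent[probe_row, , drop = FALSE] + affinity +
    matrix(stats::rnorm(length(probe_ids) * ns, 0, 1), length(probe_ids), ns) *
    sdres[probe_row]
  rownames(expr) <- probe_ids

  annotation <- data.frame(probe_id = probe_ids,
                           gene_id = as.character(probe_gene),
                           stringsAsFactors = FALSE)

  # junk probes: half unmapped, half multi-mapped
  n_junk <- round(config$frac_unmapped * length(probe_ids))
  if (n_junk > 0L && ng >= 2L) {
    junk_ids <- sprintf("junk_p%03d", seq_len(n_junk))
    junk <- matrix(stats::rnorm(n_junk * ns, 7, 1), n_junk, ns,
                   dimnames = list(junk_ids, sample_ids))
    expr <- rbind(expr, junk)
    multi <- vapply(seq_len(n_junk), function(i)
      paste(sample(genes, 2L), collapse = "///"), character(1L))
    gene_id <- ifelse(seq_len(n_junk) %% 2L == 1L, NA_character_, multi)
    annotation <- rbind(annotation,
                        data.frame(probe_id = junk_ids, gene_id = gene_id,
                                   stringsAsFactors = FALSE))
  }

  metadata <- data.frame(sample_id = sample_ids, stage = stage_of_sample,
                         stringsAsFactors = FALSE)
  block_membership <- setNames(block_of, genes)
  truth <- list(
    block_membership = setNames(
      rep(list(block_membership), length(STAGES)), STAGES),
    de_genes = de_genes,
    trend_assignment = setNames(trend_of, genes)[!is.na(trend_of)],
    outlier_samples = sample_ids[is_outlier],
    stage_offsets = offset)
  structure(list(expression = expr, metadata = metadata,
                 annotation = annotation, truth = truth, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", nrow(x$expression), "probes x", ncol(x$expression),
      "samples;", x$config$n_genes, "genes,",
      x$config$n_blocks, "blocks, seed", x$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits `expression.tsv` (probe-level, full double precision),
#' `metadata.tsv`, `probes.tsv` and `ground_truth.json`, and returns a
#' manifest of the four files with MD5 checksums. Round-trips losslessly
#' through [read_expression()], [read_metadata()] and [read_annotation()].
#'
#' @param dataset A `sim_dataset` from [generate_dataset()].
#' @param out_dir Writable output directory (created if needed).
#' @return Data frame manifest with columns `file`, `md5`.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- file.path(out_dir, c("expression.tsv", "metadata.tsv",
                                "probes.tsv", "ground_truth.json"))
  write_expression(dataset$expression, paths[1L], id_col = "probe_id")
  write_metadata(dataset$metadata, paths[2L])
  write_annotation(dataset$annotation, paths[3L])
  truth <- dataset$truth
  truth$stage_offsets <- NULL
  # named vectors must become objects, not arrays, to survive JSON
  truth$trend_assignment <- as.list(truth$trend_assignment)
  truth$block_membership <- lapply(truth$block_membership, as.list)
  jsonlite::write_json(truth, paths[4L], auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  data.frame(file = basename(paths),
             md5 = unname(tools::md5sum(paths)),
             stringsAsFactors = FALSE)
}
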