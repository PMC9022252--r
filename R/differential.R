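# Vectorized Welch t over matrix rows. Zero pooled variance: equal means give
# p = 1, unequal means give the smallest positive double (with one warning).
welch_rows <- function(X, idx_test, idx_ref) {
  nt <- length(idx_test)
  nr <- length(idx_ref)
  if (nt < 2L || nr < 2L) stop("each group needs at least 2 samples")
  Xt <- X[, idx_test, drop = FALSE]
  Xr <- X[, idx_ref, drop = FALSE]
  mt <- rowMeans(Xt)
  mr <- rowMeans(Xr)
  vt <- rowSums((Xt - mt)^2) / (nt - 1)
  vr <- rowSums((Xr - mr)^2) / (nr - 1)
  se2 <- vt / nt + vr / nr
  fc <- mt - mr
  p <- rep(NA_real_, nrow(X))
  ok <- se2 > 0
  if (any(ok)) {
    tt <- fc[ok] / sqrt(se2[ok])
    df <- se2[ok]^2 /
      ((vt[ok] / nt)^2 / (nt - 1) + (vr[ok] / nr)^2 / (nr - 1))
    p[ok] <- 2 * pt(-abs(tt), df)
  }
  degen <- !ok
  if (any(degen)) {
    eq <- degen & abs(fc) < .Machine$double.eps^0.5
    p[eq] <- 1
    forced <- degen & !eq
    if (any(forced)) {
      warning(sum(forced), " feature(s) constant within groups but with ",
              "unequal means; p set to the smallest positive double")
      p[forced] <- .Machine$double.xmin
    }
  }
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  data.frame(p_value = p, log2fc = fc, row.names = rownames(X))
}

#' Two-sample Welch t-test for one probe
#'
#' Two-sided test on log2 values; `log2fc` is mean(test) - mean(reference).
#' When both groups have zero variance the test is degenerate: equal means
#' give p = 1, unequal means give the smallest positive double with a warning.
#'
#' @param values_test,values_ref Numeric vectors (each of length >= 2).
#' @return List with elements `p_value` and `log2fc`.
#' @export
probe_test <- function(values_test, values_ref) {
  if (length(values_test) < 2L || length(values_ref) < 2L)
    stop("each group needs at least 2 samples")
  X <- matrix(c(values_test, values_ref), nrow = 1L)
  res <- welch_rows(X, seq_along(values_test),
                    length(values_test) + seq_along(values_ref))
  list(p_value = res$p_value[1L], log2fc = res$log2fc[1L])
}

#' Aggregate probe p-values to a gene p-value by geometric mean
#'
#' @param probe_ps Numeric vector of p-values in (0, 1], one per probe.
#' @return The geometric mean `exp(mean(log(p)))`.
#' @export
aggregate_gene_p <- function(probe_ps) {
  if (!length(probe_ps)) stop("empty p-value list")
  if (any(probe_ps <= 0) || any(probe_ps > 1))
    stop("p-values must lie in (0, 1]")
  if (length(probe_ps) == 1L) return(probe_ps)  # exactly itself
  exp(mean(log(probe_ps)))
}

#' Gene-level differential expression for one comparison
#'
#' Runs a per-probe Welch t-test between the two sample groups, then collapses
#' multi-probe genes: the gene p-value is the geometric mean of its probe
#' p-values and the gene log2 fold-change is the arithmetic mean of probe
#' log2 fold-changes. BH-adjusted q-values are reported alongside but never
#' used for filtering.
#'
#' @param matrix Probe-level (or gene-level, with `annotation = NULL`)
#'   expression matrix, features in rows, samples in columns.
#' @param metadata Data frame from [read_metadata()].
#' @param test,reference Stage labels of the two groups.
#' @param annotation Optional probe annotation; when NULL, features are taken
#'   to be gene ids already.
#' @return Data frame with columns `gene`, `comparison`, `p_value`, `q_value`,
#'   `log2fc`, `n_probes`, sorted by gene.
#' @export
differential_expression <- function(matrix, metadata, test, reference,
                                    annotation = NULL) {
  stage_of <- setNames(metadata$stage, metadata$sample_id)
  st <- stage_of[colnames(matrix)]
  idx_test <- which(!is.na(st) & st == test)
  idx_ref <- which(!is.na(st) & st == reference)
  if (length(idx_test) < 2L)
    stop("group '", test, "' has fewer than 2 samples")
  if (length(idx_ref) < 2L)
    stop("group '", reference, "' has fewer than 2 samples")
  probe <- welch_rows(matrix, idx_test, idx_ref)
  if (is.null(annotation)) {
    gene <- rownames(matrix)
  } else {
    gene_of <- setNames(annotation$gene_id, annotation$probe_id)
    gene <- gene_of[rownames(matrix)]
    if (anyNA(gene)) stop("matrix contains probes absent from the annotation")
  }
  groups <- split(seq_len(nrow(probe)), gene)
  groups <- groups[order(names(groups))]
  p <- vapply(groups, function(i) aggregate_gene_p(probe$p_value[i]),
              numeric(1L))
  fc <- vapply(groups, function(i) mean(probe$log2fc[i]), numeric(1L))
  np <- lengths(groups)
  data.frame(gene = names(groups),
             comparison = comparison_label(test, reference),
             p_value = unname(p),
             q_value = unname(p.adjust(p, method = "BH")),
             log2fc = unname(fc),
             n_probes = unname(np),
             stringsAsFactors = FALSE)
}

#' Differential expression along the neighboring-stage chain
#'
#' @inheritParams differential_expression
#' @return Named list of four [differential_expression()] tables
#'   (`I_vs_normal`, `II_vs_I`, `III_vs_II`, `IV_vs_III`).
#' @export
neighboring_deg <- function(matrix, metadata, annotation = NULL) {
  lapply(neighboring_comparisons(), function(cmp)
    differential_expression(matrix, metadata, cmp[["test"]],
                            cmp[["reference"]], annotation))
}

#' Master list of differentially expressed genes
#'
#' Union, across the four neighboring-stage comparisons, of genes with raw
#' p-value at or below `alpha`.
#'
#' @param results Named list of the four comparison tables from
#'   [neighboring_deg()].
#' @param alpha Raw p-value cut-off (default 0.05).
#' @return Lexicographically sorted character vector of gene ids.
#' @export
master_deg_list <- function(results, alpha = 0.05) {
  need <- names(neighboring_comparisons())
  missing <- setdiff(need, names(results))
  if (length(missing))
    stop("missing comparison(s): ", paste(missing, collapse = ", "))
  hits <- unlist(lapply(results[need], function(r) r$gene[r$p_value <= alpha]),
                 use.names = FALSE)
  sort(unique(hits))
}

#' Stage-specific biomarkers
#'
#' Genes differentially expressed (p <= `alpha`) between the given stage and
#' each of the four other groups (the other three tumor stages and normal),
#' i.e. the intersection of the four DEG sets.
#'
#' @inheritParams differential_expression
#' @param stage One of "I", "II", "III", "IV".
#' @param alpha Raw p-value cut-off (default 0.05).
#' @return Sorted character vector of gene ids.
#' @export
stage_specific_biomarkers <- function(matrix, metadata, stage, alpha = 0.05,
                                      annotation = NULL) {
  if (!stage %in% STAGES[-1L]) stop("stage must be one of I, II, III, IV")
  others <- setdiff(STAGES, stage)
  present <- unique(metadata$stage)
  missing <- setdiff(c(stage, others), present)
  if (length(missing))
    stop("missing group(s): ", paste(missing, collapse = ", "))
  sets <- lapply(others, function(o) {
    r <- differential_expression(matrix, metadata, stage, o, annotation)
    r$gene[r$p_value <= alpha]
  })
  sort(Reduce(intersect, sets))
}

#' Write a differential-expression table to TSV
#' @param result Table from [differential_expression()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential <- function(result, path) {
  write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
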