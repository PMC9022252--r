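#' Read a log2 expression matrix from TSV
#'
#' Expects a header row; column 1 holds feature (probe or gene) ids, remaining
#' columns one sample each. Values are log2 intensities.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, features in rows (rownames), samples in columns
#'   (colnames).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   fill = FALSE)
  if (ncol(df) < 1L) stop("expression file has no columns: ", path)
  feats <- as.character(df[[1L]])
  if (anyDuplicated(feats))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(feats[duplicated(feats)])[1:5], collapse = ", "))
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (length(m) && !is.numeric(m)) stop("non-numeric expression values in ", path)
  storage.mode(m) <- "double"
  rownames(m) <- feats
  m
}

#' Write an expression matrix to TSV at full double precision
#'
#' @param matrix Numeric matrix with rownames (features) and colnames
#'   (samples).
#' @param path Output path.
#' @param id_col Name for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(matrix, path, id_col = "feature_id") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(matrix)), collapse = "\t"), con)
  if (nrow(matrix)) {
    body <- apply(matrix, 1L, function(x)
      paste(sprintf("%.17g", x), collapse = "\t"))
    writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read sample metadata (sample id to stage label)
#'
#' @param path TSV with columns `sample_id` and `stage`; stage labels must be
#'   in [STAGES].
#' @return Data frame with character columns `sample_id`, `stage`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, fill = FALSE)
  need <- c("sample_id", "stage")
  if (!all(need %in% colnames(df)))
    stop("metadata must have columns sample_id, stage: ", path)
  df$sample_id <- as.character(df$sample_id)
  df$stage <- as.character(df$stage)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- which(!df$stage %in% STAGES)
  if (length(bad))
    stop("unknown stage label '", df$stage[bad[1L]], "' at metadata line ",
         bad[1L] + 1L)
  df[, need]
}

#' Write sample metadata
#' @param metadata Data frame with `sample_id` and `stage`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata[, c("sample_id", "stage")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' Probes mapping to no gene are encoded as an empty/NA `gene_id`; probes
#' mapping to several genes use the `"///"`-separated convention.
#'
#' @param path TSV with columns `probe_id`, `gene_id`.
#' @return Data frame with character columns `probe_id`, `gene_id` (NA when
#'   unmapped).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, fill = FALSE,
                   na.strings = c("NA", ""))
  need <- c("probe_id", "gene_id")
  if (!all(need %in% colnames(df)))
    stop("annotation must have columns probe_id, gene_id: ", path)
  df$probe_id <- as.character(df$probe_id)
  df$gene_id <- as.character(df$gene_id)
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe ids in annotation: ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  df[, need]
}

#' Write a probe annotation table
#' @param annotation Data frame with `probe_id`, `gene_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation[, c("probe_id", "gene_id")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then one gene per field, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (unique gene ids per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, " (need name, description, >=1 gene)")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("empty gene set at GMT line ", i)
    if (f[1L] %in% names(sets)) stop("duplicate set name at GMT line ", i)
    sets[[f[1L]]] <- genes
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a scored edge list (STRING-like PPI snapshot)
#'
#' Self-pairs are dropped; duplicate pairs (either orientation) are collapsed
#' keeping the maximum score.
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `score` (score in 0..1).
#' @return Data frame `gene_a`, `gene_b`, `score` with `gene_a < gene_b`.
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) stop("edge file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, fill = FALSE)
  need <- c("gene_a", "gene_b", "score")
  if (!all(need %in% colnames(df)))
    stop("edge list must have columns gene_a, gene_b, score: ", path)
  df$gene_a <- as.character(df$gene_a)
  df$gene_b <- as.character(df$gene_b)
  df$score <- as.numeric(df$score)
  bad <- which(is.na(df$score) | df$score < 0 | df$score > 1)
  if (length(bad))
    stop("score outside [0, 1] at edge-list line ", bad[1L] + 1L)
  scored_edges(df)
}

#' Canonicalize a scored edge list
#'
#' @param df Data frame with `gene_a`, `gene_b`, `score`.
#' @return Canonical edge list: no self-pairs, `gene_a < gene_b`, duplicates
#'   collapsed keeping the maximum score, sorted by pair.
#' @export
scored_edges <- function(df) {
  self <- df$gene_a == df$gene_b
  if (any(self)) {
    warning("dropping ", sum(self), " self-pair(s) from edge list")
    df <- df[!self, , drop = FALSE]
  }
  swap <- df$gene_a > df$gene_b
  tmp <- df$gene_a[swap]
  df$gene_a[swap] <- df$gene_b[swap]
  df$gene_b[swap] <- tmp
  key <- paste(df$gene_a, df$gene_b, sep = "\r")
  score <- tapply(df$score, key, max)
  keys <- sort(names(score))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[`, "", 1L),
                    gene_b = vapply(parts, `[`, "", 2L),
                    score = as.numeric(score[keys]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Drop probes without a unique gene mapping
#'
#' Removes probes whose annotation is missing, empty, or maps to multiple
#' genes (the `"///"` convention), as well as probes absent from the
#' annotation. Probe order is preserved. Idempotent.
#'
#' @param matrix Probe-level expression matrix (probes in rows).
#' @param annotation Data frame from [read_annotation()].
#' @return The matrix restricted to uniquely mapped probes.
#' @export
drop_unmapped_probes <- function(matrix, annotation) {
  gene_of <- setNames(annotation$gene_id, annotation$probe_id)
  g <- gene_of[rownames(matrix)]
  keep <- !is.na(g) & nzchar(g) & !grepl("///", g, fixed = TRUE)
  keep[is.na(keep)] <- FALSE
  out <- matrix[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("no uniquely mapped probes remain")
  out
}

#' Collapse probe-level values to gene level
#'
#' Summarizes multi-probe genes by the per-sample median across the gene's
#' probes (the value used for correlation networks and trend profiling).
#'
#' @param matrix Probe-level matrix (uniquely mapped probes).
#' @param annotation Data frame from [read_annotation()].
#' @return Gene-level matrix, genes sorted lexicographically.
#' @export
collapse_probes <- function(matrix, annotation) {
  gene_of <- setNames(annotation$gene_id, annotation$probe_id)
  g <- gene_of[rownames(matrix)]
  if (anyNA(g)) stop("matrix contains probes absent from the annotation")
  groups <- split(seq_len(nrow(matrix)), g)
  groups <- groups[order(names(groups))]
  out <- t(vapply(groups, function(i) {
    if (length(i) == 1L) matrix[i, ] else apply(matrix[i, , drop = FALSE], 2L, median)
  }, numeric(ncol(matrix))))
  colnames(out) <- colnames(matrix)
  out
}

#' Detect outlier samples on the first two principal components
#'
#' Genes are standardized, samples are projected onto PC1-PC2 of the
#' standardized matrix, and a sample is flagged when the robust z-score of its
#' Euclidean distance from the component-space centroid exceeds `k`:
#' `(dist - median(dist)) / mad(dist) > k`. Deterministic replacement for the
#' visual PCA/t-SNE inspection used in microarray QC.
#'
#' @param matrix Expression matrix, features in rows, samples in columns
#'   (at least 3 samples).
#' @param k Robust z-score cut-off (default 5); `Inf` flags nothing.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(matrix, k = 5) {
  if (ncol(matrix) < 3L) stop("outlier detection needs at least 3 samples")
  if (!is.finite(k)) return(character(0L))
  sds <- apply(matrix, 1L, sd)
  keep <- sds > 0
  if (!any(keep)) return(character(0L))
  z <- (matrix[keep, , drop = FALSE] - rowMeans(matrix[keep, , drop = FALSE])) /
    sds[keep]
  pc <- prcomp(t(z), center = TRUE, scale. = FALSE)
  sc <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  ctr <- colMeans(sc)
  d <- sqrt(rowSums(sweep(sc, 2L, ctr)^2))
  m <- mad(d)
  flagged <- if (m == 0) (d - median(d)) > 0 else (d - median(d)) / m > k
  colnames(matrix)[flagged]
}
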