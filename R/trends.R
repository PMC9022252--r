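#' Per-gene stage medians
#'
#' The median expression across each stage's samples, ordered along the
#' progression chain, is the representative value used for trend profiling
#' (stage groups have unequal sizes, so the median is preferred over the
#' mean).
#'
#' @param matrix Gene-level expression matrix.
#' @param metadata Data frame from [read_metadata()]; all five stages must
#'   have at least one sample among the matrix columns.
#' @return Numeric matrix, genes x 5 (columns `normal, I, II, III, IV`).
#' @export
stage_medians <- function(matrix, metadata) {
  stage_of <- setNames(metadata$stage, metadata$sample_id)
  st <- stage_of[colnames(matrix)]
  out <- vapply(STAGES, function(s) {
    cols <- which(!is.na(st) & st == s)
    if (!length(cols)) stop("stage '", s, "' has no samples")
    apply(matrix[, cols, drop = FALSE], 1L, median)
  }, numeric(nrow(matrix)))
  if (nrow(matrix) == 1L) {
    out <- matrix(out, nrow = 1L, dimnames = list(rownames(matrix), STAGES))
  }
  out
}

#' Enumerate model trend profiles
#'
#' All integer profiles of length `T` starting at 0 whose successive
#' differences are bounded by `c` in absolute value; there are `(2c+1)^(T-1)`
#' of them, returned in lexicographic order of their difference vectors.
#'
#' @param T Number of ordered conditions (default 5 stages).
#' @param c Maximum unit change between successive conditions (default 1).
#' @return Integer matrix, one profile per row (cumulative values).
#' @export
enumerate_profiles <- function(T = 5L, c = 1L) {
  if (T < 2L) stop("T must be at least 2")
  if (c < 1L) stop("c must be at least 1")
  steps <- as.matrix(expand.grid(rep(list(seq.int(-c, c)), T - 1L),
                                 KEEP.OUT.ATTRS = FALSE))
  # expand.grid varies the first column fastest; lexicographic order of the
  # difference vectors needs the first position slowest
  steps <- steps[do.call(order, as.data.frame(steps)), , drop = FALSE]
  cum <- steps
  if (ncol(cum) > 1L)
    for (j in 2:ncol(cum)) cum[, j] <- cum[, j] + cum[, j - 1L]
  prof <- cbind(0L, cum)
  dimnames(prof) <- NULL
  storage.mode(prof) <- "integer"
  prof
}

profile_string <- function(p) paste(p, collapse = ",")

# 1 - Pearson correlation, with the constant-profile conventions:
# constant vs constant -> distance 0, constant vs non-constant -> 1.
profile_distance_matrix <- function(profiles) {
  v <- apply(profiles, 1L, sd)
  const <- v == 0
  D <- matrix(1, nrow(profiles), nrow(profiles))
  if (any(!const)) {
    C <- suppressWarnings(cor(t(profiles[!const, , drop = FALSE])))
    D[!const, !const] <- 1 - C
  }
  D[const, const] <- 0
  diag(D) <- 0
  D
}

#' Greedy max-min selection of model profiles
#'
#' Selects `m` mutually dissimilar profiles under the distance
#' `1 - PearsonCorr`: the all-zero (flat) profile seeds the selection, then
#' the profile maximizing the minimum distance to the selected set is added
#' repeatedly, with ties broken by lexicographically smallest profile.
#' Deterministic. If `m` is at least the universe size, all profiles are
#' returned.
#'
#' @param universe Integer profile matrix from [enumerate_profiles()].
#' @param m Number of profiles to select (default 60).
#' @return Integer matrix of `min(m, nrow(universe))` selected profiles.
#' @export
select_profiles <- function(universe, m = 60L) {
  if (m < 1L) stop("m must be at least 1")
  nu <- nrow(universe)
  if (m >= nu) return(universe)
  lex <- do.call(order, as.data.frame(universe))
  lex_rank <- order(lex)  # rank of each row in lexicographic order
  D <- profile_distance_matrix(universe)
  flat <- which(rowSums(universe != 0L) == 0L)
  sel <- if (length(flat)) flat[1L] else lex[1L]
  mind <- D[, sel]
  for (step in seq_len(m - 1L)) {
    cand <- setdiff(seq_len(nu), sel)
    best <- cand[mind[cand] > max(mind[cand]) - 1e-12]
    pick <- best[which.min(lex_rank[best])]
    sel <- c(sel, pick)
    mind <- pmin(mind, D[, pick])
  }
  universe[sel, , drop = FALSE]
}

#' Assign genes to their best-matching trend profile
#'
#' Each gene's stage-median vector is assigned to the profile with which it
#' has maximal Pearson correlation. Conventions: a gene with a constant
#' median vector goes to the flat (all-zero) profile with score 0; the
#' correlation between a constant and a non-constant vector is 0; ties are
#' broken by lexicographically smallest profile. The score is invariant to
#' affine transforms of the median vector.
#'
#' @param medians Matrix from [stage_medians()].
#' @param profiles Integer profile matrix (e.g. from [select_profiles()]).
#' @return Data frame with columns `gene`, `profile` (comma-joined values),
#'   `score`.
#' @export
assign_genes <- function(medians, profiles) {
  if (!nrow(profiles)) stop("profiles must be non-empty")
  lex <- do.call(order, as.data.frame(profiles))
  profiles <- profiles[lex, , drop = FALSE]  # lex order: first max wins ties
  pv <- apply(profiles, 1L, sd)
  gv <- apply(medians, 1L, sd)
  C <- matrix(0, nrow(medians), nrow(profiles))
  if (any(gv > 0) && any(pv > 0)) {
    C[gv > 0, pv > 0] <- suppressWarnings(
      cor(t(medians[gv > 0, , drop = FALSE]),
          t(profiles[pv > 0, , drop = FALSE])))
  }
  flat <- which(pv == 0)
  best <- max.col(round(C, 12L), ties.method = "first")
  score <- C[cbind(seq_len(nrow(C)), best)]
  const_gene <- gv == 0
  if (any(const_gene)) {
    best[const_gene] <- if (length(flat)) flat[1L] else best[const_gene]
    score[const_gene] <- 0
  }
  data.frame(gene = rownames(medians),
             profile = apply(profiles[best, , drop = FALSE], 1L,
                             profile_string),
             score = score, stringsAsFactors = FALSE)
}

#' Is a profile string monotone non-decreasing / non-increasing?
#'
#' Helpers for interpreting [assign_genes()] output.
#'
#' @param profile Comma-joined profile string (e.g. `"0,1,1,2,2"`).
#' @return Logical.
#' @export
profile_is_nondecreasing <- function(profile) {
  vapply(strsplit(profile, ",", fixed = TRUE), function(v)
    all(diff(as.numeric(v)) >= 0), logical(1L))
}

#' @rdname profile_is_nondecreasing
#' @export
profile_is_nonincreasing <- function(profile) {
  vapply(strsplit(profile, ",", fixed = TRUE), function(v)
    all(diff(as.numeric(v)) <= 0), logical(1L))
}

#' Run the full trend analysis
#'
#' Enumerates the profile universe, selects `m` model profiles, and assigns
#' every gene by its stage medians.
#'
#' @param matrix Gene-level expression matrix.
#' @param metadata Sample metadata.
#' @param m Number of model profiles (default 60).
#' @param c Maximum unit change (default 1).
#' @return List with `profiles` (selected matrix) and `assignments` (data
#'   frame from [assign_genes()]).
#' @export
trend_analysis <- function(matrix, metadata, m = 60L, c = 1L) {
  med <- stage_medians(matrix, metadata)
  prof <- select_profiles(enumerate_profiles(length(STAGES), c), m)
  list(profiles = prof, assignments = assign_genes(med, prof))
}
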