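# Distance-based community comparisons. Bray-Curtis and Jaccard are computed
# from their closed forms; Mantel and PERMANOVA use the add-one permutation
# p-value convention p = (1 + #{stat* >= stat}) / (1 + n_permutations), or an
# exact enumeration when an explicit permutation matrix is supplied.

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))`, in `[0, 1]`.
#'
#' @param x,y Nonnegative numeric vectors of equal length, not both all-zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("abundances must be nonnegative")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("undefined-distance error: both vectors are all-zero")
  1 - 2 * sum(pmin(x, y)) / tot
}

#' Jaccard distance between two presence/absence vectors
#'
#' `1 - |intersection| / |union|`, in `[0, 1]`.
#'
#' @param a,b Logical vectors of equal length, not both all-FALSE.
#' @return Dissimilarity in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) stop("undefined-distance error: both vectors are all-absent")
  1 - sum(a & b) / u
}

#' Pairwise dissimilarity matrix over sample rows
#'
#' @param mat Samples x features matrix; abundances for `method = "bray"`,
#'   logical/0-1 for `method = "jaccard"`.
#' @param method `"bray"` or `"jaccard"`.
#' @return Symmetric n x n matrix with zero diagonal and the sample row
#'   names as labels.
#' @export
dissimilarity_matrix <- function(mat, method = c("bray", "jaccard")) {
  method <- match.arg(method)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  f <- if (method == "bray") bray_curtis else jaccard_distance
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- f(mat[i, ], mat[j, ])
    }
  }
  d
}

.upper <- function(d) d[upper.tri(d)]

.check_square <- function(d1, d2) {
  if (!identical(dim(d1), dim(d2)))
    stop("alignment error: distance matrices differ in size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop("alignment error: distance matrix labels differ")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with a one-tailed
#' (positive association) permutation p-value obtained by jointly permuting
#' the rows and columns of `d2`:
#' `p = (1 + #{r* >= r}) / (1 + n_permutations)`.
#'
#' @param d1,d2 Square symmetric distance matrices over the same samples, in
#'   the same order.
#' @param permutations Either a permutation count (default 999) or an
#'   explicit matrix with one permutation of `1:n` per row, in which case
#'   the p-value is the exact fraction of the supplied permutations
#'   (identity included) with `r* >= r`.
#' @param seed Optional RNG seed fixing the permutation draw.
#' @return List `r`, `p`, `n_permutations`, `seed`.
#' @export
mantel_test <- function(d1, d2, permutations = 999, seed = NULL) {
  .check_square(d1, d2)
  n <- nrow(d1)
  if (n < 3) stop("need at least 3 samples")
  v1 <- .upper(d1)
  r_obs <- stats::cor(v1, .upper(d2))
  stat <- function(perm) stats::cor(v1, .upper(d2[perm, perm]))
  if (is.matrix(permutations)) {
    r_perm <- apply(permutations, 1, stat)
    p <- mean(r_perm >= r_obs - 1e-12)
    nperm <- nrow(permutations)
  } else {
    if (!is.null(seed)) set.seed(seed)
    r_perm <- vapply(seq_len(permutations),
                     function(i) stat(sample.int(n)), 0)
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + permutations)
    nperm <- permutations
  }
  list(r = r_obs, p = p, n_permutations = nperm, seed = seed)
}

# Distance-based sums of squares for a grouping: SS_total = sum d^2 / n over
# all pairs; SS_within = per-group pairwise sum d^2 / n_group.
.permanova_ss <- function(d2sq, groups) {
  n <- nrow(d2sq)
  ss_total <- sum(d2sq[upper.tri(d2sq)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d2sq[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

#' One-factor PERMANOVA
#'
#' Partitions the distance-based sums of squares between and within the
#' groups, giving pseudo-F = (SS_between / df_between) / (SS_within /
#' df_within), R-squared = SS_between / SS_total, and a permutation p-value
#' obtained by shuffling the group labels:
#' `p = (1 + #{F* >= F}) / (1 + n_permutations)`.
#'
#' @param d Square symmetric distance matrix.
#' @param groups Group label per sample (>= 2 groups, none spanning the
#'   whole dataset).
#' @param permutations Permutation count (default 999) or an explicit
#'   permutation matrix as in [mantel_test()].
#' @param seed Optional RNG seed.
#' @return List `pseudo_F`, `R2`, `df`, `p`, `ss` (total/within/between),
#'   `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, permutations = 999, seed = NULL) {
  n <- nrow(d)
  if (length(groups) != n)
    stop("alignment error: one group label per sample required")
  groups <- as.character(groups)
  k <- length(unique(groups))
  if (k < 2) stop("degenerate-design error: need at least 2 groups")
  if (n < 3) stop("need at least 3 samples")
  d2sq <- d^2
  ss <- .permanova_ss(d2sq, groups)
  df_b <- k - 1L
  df_w <- n - k
  f_obs <- (ss["between"] / df_b) / (ss["within"] / df_w)
  stat <- function(perm) {
    s <- .permanova_ss(d2sq, groups[perm])
    (s["between"] / df_b) / (s["within"] / df_w)
  }
  if (is.matrix(permutations)) {
    f_perm <- apply(permutations, 1, stat)
    p <- mean(f_perm >= f_obs - 1e-12)
    nperm <- nrow(permutations)
  } else {
    if (!is.null(seed)) set.seed(seed)
    f_perm <- vapply(seq_len(permutations),
                     function(i) stat(sample.int(n)), 0)
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + permutations)
    nperm <- permutations
  }
  list(pseudo_F = unname(f_obs), R2 = unname(ss["between"] / ss["total"]),
       df = df_b, p = p, ss = ss, n_permutations = nperm, seed = seed)
}

#' Bonferroni correction
#'
#' `min(1, m * p)` across the `m` supplied p-values (delegates to
#' [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Period-wise Mantel tests with Bonferroni correction
#'
#' Runs a Mantel test within each study period separately so that no
#' individual contributes more than one sample per test: within a period the
#' latest available sample per participant is kept. The diet count matrix is
#' converted to relative abundances and compared with Bray-Curtis; the
#' comparison matrix uses Bray-Curtis for abundance data or Jaccard for a
#' logical matrix. Raw p-values are Bonferroni-corrected across the tested
#' periods. Periods with fewer than 3 usable participants are skipped with a
#' warning.
#'
#' @param counts Samples x taxa count matrix (DNA side).
#' @param other Samples x features matrix compared against `counts`: a
#'   logical diary matrix (Jaccard) or a numeric auxiliary matrix such as
#'   microbial relative abundances (Bray-Curtis).
#' @param metadata Sample metadata (`sample_id`, `participant`, `day`,
#'   `period`).
#' @param periods Period labels to test (default: all in `metadata`).
#' @param permutations,seed Passed to [mantel_test()].
#' @return Data frame with one row per tested period: `period`, `n`, `r`,
#'   `p`, `p_adjusted`, plus attribute `selected` listing the retained
#'   sample per (participant, period).
#' @export
periodwise_mantel <- function(counts, other, metadata,
                              periods = unique(metadata$period),
                              permutations = 999, seed = NULL) {
  stopifnot(all(c("sample_id", "participant", "day", "period") %in%
                  names(metadata)))
  rows <- list()
  selected <- list()
  for (per in periods) {
    meta <- metadata[metadata$period == per &
                       metadata$sample_id %in% rownames(counts) &
                       metadata$sample_id %in% rownames(other), , drop = FALSE]
    meta <- meta[rowSums(counts[meta$sample_id, , drop = FALSE]) > 0, ,
                 drop = FALSE]
    meta <- meta[order(meta$participant, -meta$day), , drop = FALSE]
    meta <- meta[!duplicated(meta$participant), , drop = FALSE]
    if (nrow(meta) < 3) {
      warning("period '", per, "' skipped: fewer than 3 usable participants")
      next
    }
    ids <- meta$sample_id
    selected[[per]] <- meta
    rel <- counts[ids, , drop = FALSE]
    rel <- sweep(rel, 1, rowSums(rel), "/")
    d1 <- dissimilarity_matrix(rel, "bray")
    oth <- other[ids, , drop = FALSE]
    d2 <- if (is.logical(other)) dissimilarity_matrix(oth, "jaccard")
          else dissimilarity_matrix(oth, "bray")
    res <- mantel_test(d1, d2, permutations = permutations, seed = seed)
    rows[[per]] <- data.frame(period = per, n = length(ids), r = res$r,
                              p = res$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(period = character(0), n = integer(0), r = numeric(0),
                      p = numeric(0), p_adjusted = numeric(0)))
  out$p_adjusted <- bonferroni(out$p)
  rownames(out) <- NULL
  attr(out, "selected") <- selected
  out
}
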