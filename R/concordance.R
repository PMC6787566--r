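# Concordance between DNA detections and diet records. All metrics are
# micro-averaged: TP/FP/FN are pooled over every (sample, taxon) cell of the
# subset before forming recall = TP/(TP+FN) and precision = TP/(TP+FP).

#' Round half away from zero
#'
#' Commercial rounding used when rendering report values (base `round()`
#' rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' F-measure: harmonic mean of recall and precision
#'
#' `2 * r * p / (r + p)`, defined as 0 when both inputs are 0. Ranges from 0
#' (completely inaccurate detection) to 1 (perfect recall and precision) and
#' tends toward the lesser of the two inputs.
#'
#' @param recall,precision Proportions in `[0, 1]` (vectorised).
#' @return Numeric vector of F-measures.
#' @export
#' @examples
#' f_measure(0.76, 0.26)  # 0.39 at two decimals
f_measure <- function(recall, precision) {
  if (any(recall < 0 | recall > 1 | precision < 0 | precision > 1,
          na.rm = TRUE))
    stop("domain error: recall and precision must lie in [0, 1]")
  out <- ifelse(recall + precision == 0, 0,
                2 * recall * precision / (recall + precision))
  out
}

#' Detection from a count table at a relative-abundance threshold
#'
#' A taxon is called present in a sample when its count strictly exceeds
#' `tau` times the sample's total assigned reads; `tau = 0` means any
#' nonzero count. Samples with zero total (failed amplifications) are
#' excluded from the result.
#'
#' @param count_table Samples x taxa count matrix.
#' @param tau Relative-abundance threshold in `[0, 1)`; presence requires
#'   `count / total > tau`.
#' @return Logical matrix over the retained samples.
#' @export
detect_presence <- function(count_table, tau = 0) {
  if (tau < 0 || tau >= 1) stop("domain error: tau must lie in [0, 1)")
  totals <- rowSums(count_table)
  keep <- totals > 0
  m <- count_table[keep, , drop = FALSE]
  sweep(m, 1, rowSums(m), "/") > tau
}

#' Aggregate a matrix to a taxonomic level
#'
#' Collapses columns to their ancestor at `level`: read counts are summed;
#' logical (presence/absence) entries are combined with OR. Taxa with no
#' ancestor at the requested level (e.g. a multi-genus group when `level =
#' "genus"`) are excluded from the comparison; the number of columns that
#' remain is reported as the `n_taxa_in_comparison` attribute. `level =
#' "all"` returns the matrix unchanged, mixing native ranks side by side.
#'
#' @param mat Numeric count matrix or logical presence matrix, columns named
#'   by taxid.
#' @param taxonomy Taxonomy table (`taxid`, `name`, `rank`, `parent`).
#' @param level `"all"`, `"species"`, `"genus"`, or `"family"`.
#' @return Matrix at the requested level, with attribute
#'   `n_taxa_in_comparison`.
#' @export
aggregate_taxa <- function(mat, taxonomy, level = "all") {
  if (!level %in% c("all", "species", "genus", "family"))
    stop("domain error: unknown level '", level, "'")
  if (level == "all") {
    attr(mat, "n_taxa_in_comparison") <- ncol(mat)
    return(mat)
  }
  anc <- vapply(colnames(mat), .ancestor_at, "", taxonomy = taxonomy,
                rank = level)
  keep <- !is.na(anc)
  groups <- sort(unique(anc[keep]))
  logical_in <- is.logical(mat)
  out <- matrix(if (logical_in) FALSE else 0, nrow = nrow(mat),
                ncol = length(groups), dimnames = list(rownames(mat), groups))
  for (g in groups) {
    cols <- which(keep & anc == g)
    block <- mat[, cols, drop = FALSE]
    out[, g] <- if (logical_in) rowSums(block) > 0 else rowSums(block)
  }
  attr(out, "n_taxa_in_comparison") <- length(groups)
  out
}

#' Pooled concordance between detections and diary
#'
#' Pools true positives, false positives, and false negatives over all
#' (sample, taxon) cells of the chosen subset and reports micro-averaged
#' recall (fraction of diary-recorded foods also detected by sequencing),
#' precision (fraction of detected taxa also recorded), and their harmonic
#' mean.
#'
#' @param detections Logical samples x taxa matrix (DNA side).
#' @param diary Logical samples x taxa matrix (record side), same vocabulary.
#' @param subset Optional character vector of sample ids restricting the
#'   comparison (must be nonempty after intersection with both matrices).
#' @param label Subset label carried into the report.
#' @return A `concordance_report` list: `tp`, `fp`, `fn`, `recall`,
#'   `precision`, `fmeasure`, `n_samples`, `n_taxa`, `label`.
#' @export
concordance_metrics <- function(detections, diary, subset = NULL,
                                label = "all samples") {
  samples <- intersect(rownames(detections), rownames(diary))
  if (!is.null(subset)) samples <- intersect(samples, subset)
  if (!length(samples)) stop("alignment error: no samples in common")
  if (!identical(sort(colnames(detections)), sort(colnames(diary))))
    stop("alignment error: detection and diary taxa differ")
  d <- detections[samples, sort(colnames(detections)), drop = FALSE]
  r <- diary[samples, sort(colnames(diary)), drop = FALSE]
  tp <- sum(d & r)
  fp <- sum(d & !r)
  fn <- sum(!d & r)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  fm <- if (!is.na(recall) && !is.na(precision))
    f_measure(recall, precision) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, recall = recall,
                 precision = precision, fmeasure = fm,
                 n_samples = length(samples), n_taxa = ncol(d),
                 label = label),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "Concordance (%s): TP=%d FP=%d FN=%d | recall=%.2f precision=%.2f F=%.2f\n",
    x$label, x$tp, x$fp, x$fn, round_half_up(x$recall),
    round_half_up(x$precision), round_half_up(x$fmeasure)))
  invisible(x)
}

#' Per-taxon false-positive and false-negative rates
#'
#' For each taxon, over the subset samples: FPR = FP / (FP + TN) and FNR =
#' FN / (FN + TP). FNR is NA when the taxon never appears in the diary (its
#' denominator is 0). A taxon detected in every sample whose diary also
#' records it everywhere has no negatives of either kind; by convention it
#' reports FPR = 1 and FNR = 0.
#'
#' @inheritParams concordance_metrics
#' @return Data frame with one row per taxon: `taxid`, `n_detected`,
#'   `n_diary`, `fpr`, `fnr`; attribute `n_high_fpr` counts taxa with
#'   FPR > 0.5.
#' @export
taxon_error_rates <- function(detections, diary, subset = NULL) {
  samples <- intersect(rownames(detections), rownames(diary))
  if (!is.null(subset)) samples <- intersect(samples, subset)
  taxa <- sort(colnames(detections))
  d <- detections[samples, taxa, drop = FALSE]
  r <- diary[samples, taxa, drop = FALSE]
  tp <- colSums(d & r); fp <- colSums(d & !r)
  fn <- colSums(!d & r); tn <- colSums(!d & !r)
  fpr <- ifelse(fp + tn > 0, fp / (fp + tn), NA_real_)
  fnr <- ifelse(fn + tp > 0, fn / (fn + tp), NA_real_)
  fnr[colSums(r) == 0] <- NA_real_
  all_detected <- colSums(d) == length(samples)
  fpr[all_detected & fp + tn == 0] <- 1
  fnr[all_detected & fn + tp == 0] <- 0
  out <- data.frame(taxid = taxa, n_detected = colSums(d),
                    n_diary = colSums(r), fpr = fpr, fnr = fnr,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_high_fpr") <- sum(out$fpr > 0.5, na.rm = TRUE)
  out
}

#' Three-way partition of taxa across the two methods
#'
#' Over the whole dataset, classifies each taxon as detected by both
#' sequencing and diary, sequencing only, or diary only (presence meaning
#' detected/recorded at least once anywhere), with percentages of the union
#' rounded to whole percent.
#'
#' @param detections,diary Logical samples x taxa matrices, or character
#'   vectors of taxa observed at least once.
#' @return List `n_both`, `n_dna_only`, `n_diary_only`, `pct_both`,
#'   `pct_dna_only`, `pct_diary_only`.
#' @export
venn_partition <- function(detections, diary) {
  as_set <- function(x) {
    if (is.matrix(x)) colnames(x)[colSums(x) > 0] else unique(as.character(x))
  }
  dna <- as_set(detections)
  rec <- as_set(diary)
  n_both <- length(intersect(dna, rec))
  n_dna <- length(setdiff(dna, rec))
  n_diary <- length(setdiff(rec, dna))
  union_n <- n_both + n_dna + n_diary
  pct <- function(n) if (union_n > 0) round_half_up(100 * n / union_n, 0) else NA_real_
  list(n_both = n_both, n_dna_only = n_dna, n_diary_only = n_diary,
       pct_both = pct(n_both), pct_dna_only = pct(n_dna),
       pct_diary_only = pct(n_diary))
}

#' Concordance grid over subsets, taxonomic levels, and thresholds
#'
#' Evaluates the pooled concordance metrics for every combination of sample
#' subset, taxonomic level, and relative-abundance threshold, reproducing the
#' standard benchmarking grid: counts are aggregated to the level (summing),
#' the diary is aggregated with OR, detection is called at each threshold on
#' the aggregated counts, and metrics are pooled over the subset.
#'
#' @param count_table Samples x taxa count matrix.
#' @param diary Logical samples x taxa diary matrix (same vocabulary).
#' @param taxonomy Taxonomy table.
#' @param subsets Named list of sample-id vectors (default: one subset with
#'   every sample).
#' @param levels Taxonomic levels (default `c("all", "species", "genus",
#'   "family")`).
#' @param thresholds Relative-abundance thresholds (default
#'   `c(0, 0.01, 0.05)`).
#' @return Data frame with one row per (subset, level, threshold):
#'   `subset`, `level`, `threshold`, `n_samples`, `n_taxa_in_comparison`,
#'   `tp`, `fp`, `fn`, `recall`, `precision`, `fmeasure`.
#' @export
metric_grid <- function(count_table, diary, taxonomy,
                        subsets = list(`all samples` = rownames(count_table)),
                        levels = c("all", "species", "genus", "family"),
                        thresholds = c(0, 0.01, 0.05)) {
  rows <- list()
  for (lev in levels) {
    cnt_l <- aggregate_taxa(count_table, taxonomy, lev)
    diary_l <- aggregate_taxa(diary, taxonomy, lev)
    n_taxa <- attr(cnt_l, "n_taxa_in_comparison")
    for (tau in thresholds) {
      det <- detect_presence(cnt_l, tau)
      for (sub in names(subsets)) {
        rep <- concordance_metrics(det, diary_l, subset = subsets[[sub]],
                                   label = sub)
        rows[[length(rows) + 1L]] <- data.frame(
          subset = sub, level = lev, threshold = tau,
          n_samples = rep$n_samples, n_taxa_in_comparison = n_taxa,
          tp = rep$tp, fp = rep$fp, fn = rep$fn,
          recall = rep$recall, precision = rep$precision,
          fmeasure = rep$fmeasure, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
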