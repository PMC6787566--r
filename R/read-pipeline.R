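# Reads are carried through the pipeline as a plain data frame with columns
# read_id, sequence, quality (Phred+33 string), plus sample_id after
# demultiplexing. read_fastq()/write_fastq() convert to and from FASTQ.

#' Read quality filter parameters
#'
#' Thresholds applied during read screening. Defaults follow the standard P6
#' processing recipe: at most 2 mismatches per primer site; reads whose
#' extracted P6 region has mean Phred quality <= `min_mean_quality` are
#' removed (the comparison is non-strict, so a mean of exactly 32 is
#' rejected); any ambiguous base call in the P6 region rejects the read; P6
#' regions shorter than `min_length` are rejected; unique sequences occurring
#' fewer than `min_global_count` times across the whole run are dropped.
#'
#' @param max_primer_mismatch Mismatches tolerated per primer site (default 2).
#' @param min_mean_quality Mean-quality cutoff; reads averaging at or below
#'   this are removed (default 32).
#' @param min_length Minimum P6 length in bp (default 9).
#' @param min_global_count Global count floor across all samples (default 10).
#' @param allow_ambiguous Permit non-ACGT bases in the P6 region (default
#'   FALSE).
#' @return A `filter_params` list.
#' @export
filter_params <- function(max_primer_mismatch = 2L, min_mean_quality = 32,
                          min_length = 9L, min_global_count = 10L,
                          allow_ambiguous = FALSE) {
  if (max_primer_mismatch < 0 || min_mean_quality < 0 || min_length < 0 ||
      min_global_count < 0)
    stop("filter thresholds must be >= 0")
  structure(list(max_primer_mismatch = as.integer(max_primer_mismatch),
                 min_mean_quality = min_mean_quality,
                 min_length = as.integer(min_length),
                 min_global_count = as.integer(min_global_count),
                 allow_ambiguous = isTRUE(allow_ambiguous)),
            class = "filter_params")
}

#' Read single-end FASTQ into the pipeline's read table
#'
#' @param path FASTQ file (Phred+33).
#' @return Data frame with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  # the reader warns about dropping (empty) metadata columns
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write the pipeline's read table as FASTQ
#'
#' @param reads Data frame with `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  # the constructor warns about dropping (empty) metadata columns
  x <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(reads$sequence, reads$read_id)),
    Biostrings::PhredQuality(reads$quality)))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Demultiplex reads by 5' MID tag
#'
#' Assigns each read to a sample by exact match of a molecular identification
#' (MID) tag at the 5' end and strips the tag from sequence and qualities.
#' Reads matching no tag are discarded and counted. When tags of different
#' lengths could both match, the longest tag wins.
#'
#' @param reads Read table (`read_id`, `sequence`, `quality`).
#' @param mid_map Data frame with columns `mid` and `sample_id`, one row per
#'   tag; a tag may map to only one sample.
#' @return List with `reads` (read table plus `sample_id`, tags stripped),
#'   `n_unmatched`, and `samples` (all sample ids in the map).
#' @export
demultiplex <- function(reads, mid_map) {
  stopifnot(all(c("mid", "sample_id") %in% names(mid_map)))
  if (anyDuplicated(mid_map$mid))
    stop("config error: duplicate MID tag in map")
  ord <- order(-nchar(mid_map$mid))
  sample_of <- rep(NA_character_, nrow(reads))
  taglen <- integer(nrow(reads))
  for (i in ord) {
    tag <- mid_map$mid[i]
    hit <- is.na(sample_of) & startsWith(reads$sequence, tag)
    sample_of[hit] <- mid_map$sample_id[i]
    taglen[hit] <- nchar(tag)
  }
  keep <- !is.na(sample_of)
  out <- reads[keep, , drop = FALSE]
  out$sequence <- substring(out$sequence, taglen[keep] + 1L)
  out$quality <- substring(out$quality, taglen[keep] + 1L)
  out$sample_id <- sample_of[keep]
  rownames(out) <- NULL
  list(reads = out, n_unmatched = sum(!keep),
       samples = unique(mid_map$sample_id))
}

#' Locate primers and screen reads
#'
#' For each demultiplexed read, locates the forward primer site and the
#' downstream reverse-primer binding site (ungapped, IUPAC-aware on the
#' primer side, at most `max_primer_mismatch` mismatches each), extracts the
#' inter-primer P6 region with its qualities, and applies the quality,
#' ambiguity, and length filters. Rejections are data, not errors: each
#' rejected read is recorded with its reason (`primer`, `quality`,
#' `ambiguous`, or `length`).
#'
#' @param reads Demultiplexed read table (with `sample_id`).
#' @param primers A [primer_pair()].
#' @param params A [filter_params()].
#' @return List with `passed` (data frame `read_id`, `sample_id`, `p6`,
#'   `p6_quality`, `mean_quality`) and `rejected` (data frame `read_id`,
#'   `sample_id`, `reason`).
#' @export
screen_reads <- function(reads, primers = trnl_p6_primers(),
                         params = filter_params()) {
  n <- nrow(reads)
  empty_pass <- data.frame(read_id = character(0), sample_id = character(0),
                           p6 = character(0), p6_quality = character(0),
                           mean_quality = numeric(0), stringsAsFactors = FALSE)
  if (!n) return(list(passed = empty_pass,
                      rejected = data.frame(read_id = character(0),
                                            sample_id = character(0),
                                            reason = character(0))))
  mm <- params$max_primer_mismatch
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  f_hits <- Biostrings::vmatchPattern(primers$forward, seqs,
                                      max.mismatch = mm, fixed = "subject")
  r_hits <- Biostrings::vmatchPattern(revcomp(primers$reverse), seqs,
                                      max.mismatch = mm, fixed = "subject")
  f_start <- vapply(Biostrings::startIndex(f_hits),
                    function(s) if (length(s)) min(s) else NA_integer_, 0L)
  f_end <- f_start + nchar(primers$forward) - 1L
  r_list <- Biostrings::startIndex(r_hits)
  r_start <- rep(NA_integer_, n)
  for (i in which(!is.na(f_start))) {
    s <- r_list[[i]]
    s <- s[s > f_end[i]]
    if (length(s)) r_start[i] <- min(s)
  }

  reason <- rep(NA_character_, n)
  reason[is.na(f_start) | is.na(r_start)] <- "primer"
  ok <- is.na(reason)
  p6 <- rep(NA_character_, n)
  p6q <- rep(NA_character_, n)
  meanq <- rep(NA_real_, n)
  p6[ok] <- substring(reads$sequence[ok], f_end[ok] + 1L, r_start[ok] - 1L)
  p6q[ok] <- substring(reads$quality[ok], f_end[ok] + 1L, r_start[ok] - 1L)
  meanq[ok] <- vapply(p6q[ok], function(q) {
    if (!nzchar(q)) return(NA_real_)
    mean(utf8ToInt(q)) - 33
  }, 0, USE.NAMES = FALSE)

  zerolen <- ok & !nzchar(p6)
  reason[zerolen] <- "length"
  ok <- is.na(reason)
  reason[ok & meanq <= params$min_mean_quality] <- "quality"
  ok <- is.na(reason)
  if (!params$allow_ambiguous)
    reason[ok & grepl("[^ACGT]", p6)] <- "ambiguous"
  ok <- is.na(reason)
  reason[ok & nchar(p6) < params$min_length] <- "length"
  ok <- is.na(reason)

  passed <- data.frame(read_id = reads$read_id[ok],
                       sample_id = reads$sample_id[ok],
                       p6 = p6[ok], p6_quality = p6q[ok],
                       mean_quality = meanq[ok],
                       stringsAsFactors = FALSE, row.names = NULL)
  rejected <- data.frame(read_id = reads$read_id[!ok],
                         sample_id = reads$sample_id[!ok],
                         reason = reason[!ok],
                         stringsAsFactors = FALSE, row.names = NULL)
  list(passed = passed, rejected = rejected)
}

#' Dereplicate screened reads and apply the global count floor
#'
#' Tallies identical P6 sequences across the entire run (all samples,
#' including any controls or blanks) and drops unique sequences whose total
#' count falls below `min_global_count`. The floor is global and applied
#' once, before taxonomic assignment.
#'
#' @param passed `passed` data frame from [screen_reads()].
#' @param params A [filter_params()] (supplies `min_global_count`).
#' @return List with `counts` (data frame `sequence`, `sample_id`, `count`
#'   for retained sequences), `n_below_floor` (reads dropped by the floor),
#'   `n_unique_kept`, `n_unique_dropped`.
#' @export
dereplicate_and_floor <- function(passed, params = filter_params()) {
  if (!nrow(passed))
    return(list(counts = data.frame(sequence = character(0),
                                    sample_id = character(0),
                                    count = integer(0)),
                n_below_floor = 0L, n_unique_kept = 0L, n_unique_dropped = 0L))
  tab <- stats::aggregate(count ~ sequence + sample_id,
                          data = data.frame(sequence = passed$p6,
                                            sample_id = passed$sample_id,
                                            count = 1L),
                          FUN = sum)
  totals <- tapply(tab$count, tab$sequence, sum)
  keep_seq <- names(totals)[totals >= params$min_global_count]
  kept <- tab[tab$sequence %in% keep_seq, , drop = FALSE]
  rownames(kept) <- NULL
  list(counts = kept,
       n_below_floor = sum(tab$count) - sum(kept$count),
       n_unique_kept = length(keep_seq),
       n_unique_dropped = length(totals) - length(keep_seq))
}

#' Assign unique sequences to taxa by exact match
#'
#' Retains only sequences with 100% identity to a reference-database entry;
#' each matching sequence contributes its counts to the curated taxon of the
#' byte-identical entry. A taxon may be fed by several haplotypes; their
#' counts are summed. Non-matching sequences are reported with their counts.
#'
#' @param derep Output of [dereplicate_and_floor()] (or its `counts` frame).
#' @param db A `reference_db`.
#' @param samples Optional character vector of all run samples; samples with
#'   zero assigned reads are flagged as failed.
#' @return List with `counts` (samples x taxa integer matrix), `unassigned`
#'   (data frame `sequence`, `count`), `n_assigned`, `n_unassigned`, and
#'   `failed_samples`.
#' @export
assign_exact <- function(derep, db, samples = NULL) {
  stopifnot(inherits(db, "reference_db"))
  if (!nrow(db$entries)) stop("empty-reference error: database has no entries")
  counts <- if (is.data.frame(derep)) derep else derep$counts
  taxa <- sort(unique(db$entries$taxid))
  samples <- sort(unique(c(samples, counts$sample_id)))
  mat <- matrix(0L, nrow = length(samples), ncol = length(taxa),
                dimnames = list(samples, taxa))
  hit <- match(counts$sequence, db$entries$sequence)
  assigned <- !is.na(hit)
  if (any(assigned)) {
    tx <- db$entries$taxid[hit[assigned]]
    idx <- cbind(match(counts$sample_id[assigned], samples),
                 match(tx, taxa))
    for (k in seq_len(nrow(idx)))
      mat[idx[k, 1], idx[k, 2]] <- mat[idx[k, 1], idx[k, 2]] +
        counts$count[assigned][k]
  }
  un <- counts[!assigned, , drop = FALSE]
  unassigned <- if (nrow(un)) {
    agg <- stats::aggregate(count ~ sequence, data = un, FUN = sum)
    agg[order(-agg$count), , drop = FALSE]
  } else data.frame(sequence = character(0), count = integer(0))
  rownames(unassigned) <- NULL
  list(counts = mat, unassigned = unassigned,
       n_assigned = sum(counts$count[assigned]),
       n_unassigned = sum(un$count),
       failed_samples = samples[rowSums(mat) == 0])
}

#' Summarise a processed run
#'
#' Reports per-sample totals, the fraction of post-floor reads that matched
#' the reference exactly, per-taxon totals with the median per-taxon depth,
#' and the number of taxa detected per rank (when a taxonomy is supplied).
#'
#' @param count_table Samples x taxa count matrix.
#' @param unassigned Either the unassigned data frame from [assign_exact()]
#'   or a single total of unassigned post-floor reads.
#' @param rejections Optional rejection data frame from [screen_reads()].
#' @param taxonomy Optional taxonomy table used to tabulate detected taxa by
#'   rank.
#' @return A `run_summary` list.
#' @export
summarize_run <- function(count_table, unassigned = 0L, rejections = NULL,
                          taxonomy = NULL) {
  n_unassigned <- if (is.data.frame(unassigned)) sum(unassigned$count)
                  else sum(unassigned)
  n_assigned <- sum(count_table)
  taxon_totals <- colSums(count_table)
  detected <- taxon_totals[taxon_totals > 0]
  out <- list(
    n_assigned = n_assigned,
    n_post_floor = n_assigned + n_unassigned,
    matched_fraction = if (n_assigned + n_unassigned > 0)
      n_assigned / (n_assigned + n_unassigned) else NA_real_,
    sample_totals = rowSums(count_table),
    taxon_totals = taxon_totals,
    n_taxa_detected = length(detected),
    median_taxon_depth = if (length(detected)) stats::median(detected)
                         else NA_real_)
  if (!is.null(taxonomy)) {
    rk <- taxonomy$rank[match(names(detected), taxonomy$taxid)]
    out$taxa_per_rank <- table(rk)
  }
  if (!is.null(rejections)) out$rejections <- table(rejections$reason)
  class(out) <- "run_summary"
  out
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Metabarcoding run summary\n")
  cat(sprintf("  assigned reads:    %d of %d post-floor (%.1f%% matched)\n",
              x$n_assigned, x$n_post_floor, 100 * x$matched_fraction))
  cat("  taxa detected:     ", x$n_taxa_detected,
      " (median depth ", x$median_taxon_depth, ")\n", sep = "")
  invisible(x)
}

#' Run the full read-processing pipeline
#'
#' Demultiplexes, screens, dereplicates with the global count floor, and
#' assigns reads by exact match, returning the sample x taxon count table
#' together with rejection accounting that conserves every input read.
#'
#' @param reads Read table (see [read_fastq()]) or path to a FASTQ file.
#' @param mid_map Data frame `mid`, `sample_id` (or path to its TSV).
#' @param db A `reference_db`.
#' @param primers A [primer_pair()].
#' @param params A [filter_params()].
#' @return A `metabarcoding_run` list: `counts`, `unassigned`, `rejected`,
#'   `failed_samples`, `summary`, and `conservation` (named read counts per
#'   fate, summing to the input).
#' @export
process_reads <- function(reads, mid_map, db, primers = trnl_p6_primers(),
                          params = filter_params()) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  if (is.character(mid_map) && length(mid_map) == 1L)
    mid_map <- utils::read.delim(mid_map, stringsAsFactors = FALSE)
  n_input <- nrow(reads)
  dmx <- demultiplex(reads, mid_map)
  scr <- screen_reads(dmx$reads, primers, params)
  drp <- dereplicate_and_floor(scr$passed, params)
  asn <- assign_exact(drp, db, samples = dmx$samples)
  conservation <- c(unmatched_tag = dmx$n_unmatched,
                    rejected = nrow(scr$rejected),
                    below_floor = drp$n_below_floor,
                    unassigned = asn$n_unassigned,
                    assigned = asn$n_assigned)
  stopifnot(sum(conservation) == n_input)
  structure(list(counts = asn$counts, unassigned = asn$unassigned,
                 rejected = scr$rejected,
                 failed_samples = asn$failed_samples,
                 summary = summarize_run(asn$counts, asn$unassigned,
                                         scr$rejected, db$taxonomy),
                 conservation = conservation),
            class = "metabarcoding_run")
}
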