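#' In-silico PCR: locate amplicons between primer binding sites
#'
#' Searches a template sequence, on both strands, for sites matching the
#' forward primer and the reverse-primer binding site (the reverse complement
#' of the reverse primer) with at most `max_mismatch` ungapped mismatches per
#' primer, and reports every inter-primer region whose length falls within
#' `length_bounds`. Matching is IUPAC-degenerate on the primer side only; an
#' `N` in the template never counts as a match. The reported amplicon excludes
#' the primer sequences and is given in forward-primer orientation;
#' coordinates are 0-based half-open on the input sequence.
#'
#' @param sequence Template nucleotide string (A/C/G/T/N).
#' @param primers A [primer_pair()].
#' @param max_mismatch Maximum mismatches tolerated per primer site
#'   (default: the pair's `max_mismatch_db`).
#' @param length_bounds Inclusive `[min, max]` bounds on the inter-primer
#'   amplicon length (default `c(9, 300)`).
#'
#' @return A data frame with columns `amplicon`, `start`, `end`, `strand`
#'   (`"+"` or `"-"`), `length`; zero rows if no amplicon is found.
#' @export
#' @examples
#' p <- trnl_p6_primers()
#' tmpl <- paste0(p$forward, strrep("AT", 10), revcomp(p$reverse))
#' insilico_pcr(tmpl, p, max_mismatch = 0)
insilico_pcr <- function(sequence, primers,
                         max_mismatch = primers$max_mismatch_db,
                         length_bounds = c(9L, 300L)) {
  stopifnot(inherits(primers, "primer_pair"))
  if (length(length_bounds) != 2L || length_bounds[1] < 1 ||
      length_bounds[2] < length_bounds[1])
    stop("length_bounds must be [min, max] with min >= 1")
  empty <- data.frame(amplicon = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (is.null(sequence) || !nzchar(sequence)) return(empty)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("malformed template: characters outside A/C/G/T/N")

  n <- nchar(sequence)
  scan_strand <- function(s, strand) {
    code <- .encode_template(s)
    f_starts <- .primer_hits(code, primers$forward, max_mismatch)
    r_starts <- .primer_hits(code, revcomp(primers$reverse), max_mismatch)
    if (!length(f_starts) || !length(r_starts)) return(empty)
    Lf <- nchar(primers$forward)
    out <- vector("list", length(f_starts))
    for (i in seq_along(f_starts)) {
      fe <- f_starts[i] + Lf - 1L               # last base of forward site
      rs <- r_starts[r_starts > fe]             # reverse sites downstream
      len <- rs - fe - 1L
      keep <- len >= length_bounds[1] & len <= length_bounds[2]
      rs <- rs[keep]; len <- len[keep]
      if (!length(rs)) next
      amp <- substring(s, fe + 1L, rs - 1L)
      # 0-based half-open on this strand's coordinates
      s0 <- rep.int(fe, length(rs))
      e0 <- rs - 1L
      if (strand == "-") {                      # map back to input coords
        tmp <- n - e0
        e0 <- n - s0
        s0 <- tmp
      }
      out[[i]] <- data.frame(amplicon = amp, start = s0, end = e0,
                             strand = strand, length = len,
                             stringsAsFactors = FALSE)
    }
    out <- out[!vapply(out, is.null, TRUE)]
    if (!length(out)) return(empty)
    do.call(rbind, out)
  }

  res <- rbind(scan_strand(sequence, "+"),
               scan_strand(revcomp(sequence), "-"))
  rownames(res) <- NULL
  res
}
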