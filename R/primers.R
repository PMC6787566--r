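# IUPAC degeneracy sets used for primer-side matching. A template base other
# than A/C/G/T (e.g. N) never satisfies a primer position.
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Define a primer pair
#'
#' Bundles the forward and reverse primers used for amplification together
#' with the mismatch tolerances applied during reference-database construction
#' and during read screening. Both primers are given 5'->3'; the reverse
#' primer is written on the opposite strand, as on an oligo order sheet.
#'
#' @param forward Forward primer, IUPAC nucleotide string.
#' @param reverse Reverse primer, IUPAC nucleotide string (5'->3' on the
#'   opposite strand).
#' @param max_mismatch_db Mismatches tolerated per primer site when searching
#'   reference sequences (default 4).
#' @param max_mismatch_read Mismatches tolerated per primer site when
#'   screening sequencing reads (default 2).
#'
#' @return A `primer_pair` object (list with the four fields above).
#' @export
#' @examples
#' primer_pair("GGGCAATCCTGAGCCAA", "CCATTGAGTCTCTGCACCTATC")
primer_pair <- function(forward, reverse, max_mismatch_db = 4L,
                        max_mismatch_read = 2L) {
  forward <- toupper(forward)
  reverse <- toupper(reverse)
  if (nchar(forward) == 0L || nchar(reverse) == 0L)
    stop("primers must be nonempty")
  bad <- setdiff(unique(strsplit(paste0(forward, reverse), "")[[1]]),
                 names(IUPAC_CODES))
  if (length(bad))
    stop("primer contains non-IUPAC characters: ", paste(bad, collapse = ", "))
  if (max_mismatch_db < 0 || max_mismatch_read < 0)
    stop("mismatch limits must be >= 0")
  structure(list(forward = forward, reverse = reverse,
                 max_mismatch_db = as.integer(max_mismatch_db),
                 max_mismatch_read = as.integer(max_mismatch_read)),
            class = "primer_pair")
}

#' The trnL(UAA)-P6 "g"/"h" primer pair
#'
#' The universal plant primers amplifying the P6 loop of the chloroplast trnL
#' (UAA) intron, the short broad-spectrum marker used for plant dietary
#' metabarcoding.
#'
#' @inheritParams primer_pair
#' @return A [primer_pair()].
#' @export
trnl_p6_primers <- function(max_mismatch_db = 4L, max_mismatch_read = 2L) {
  primer_pair("GGGCAATCCTGAGCCAA", "CCATTGAGTCTCTGCACCTATC",
              max_mismatch_db = max_mismatch_db,
              max_mismatch_read = max_mismatch_read)
}

#' Reverse complement of nucleotide strings
#'
#' IUPAC-aware reverse complement operating on plain character vectors.
#'
#' @param x Character vector of IUPAC nucleotide strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

# Encode a template string as integer codes 1..4 for A,C,G,T; 5 for anything
# else (treated as matching no primer position).
.encode_template <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  code <- match(chars, c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  code
}

# All start positions (1-based) where `primer` matches the encoded template
# with <= max_mismatch Hamming mismatches, IUPAC-degenerate on the primer side.
.primer_hits <- function(tmpl_code, primer, max_mismatch) {
  L <- nchar(primer)
  n <- length(tmpl_code)
  if (n < L) return(integer(0))
  pchars <- strsplit(primer, "")[[1]]
  allow <- matrix(FALSE, nrow = 5L, ncol = L)
  for (j in seq_len(L)) {
    allowed <- IUPAC_CODES[[pchars[j]]]
    allow[match(allowed, c("A", "C", "G", "T")), j] <- TRUE
  }
  nw <- n - L + 1L
  mm <- integer(nw)
  for (j in seq_len(L)) {
    mm <- mm + !allow[cbind(tmpl_code[j:(j + nw - 1L)], j)]
  }
  which(mm <= max_mismatch)
}
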