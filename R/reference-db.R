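# Taxonomy tables are data frames with columns taxid, name, rank, parent.
# Ranks used: "family", "genus", "species", and "multigenus" for combined
# multi-genus groups created during curation (parent = the shared family).

.check_taxonomy <- function(taxonomy) {
  need <- c("taxid", "name", "rank", "parent")
  if (!all(need %in% names(taxonomy)))
    stop("taxonomy must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(taxonomy$taxid))
    stop("taxonomy error: duplicated taxid")
  invisible(taxonomy)
}

# Walk to the ancestor of `taxid` at `rank`; NA if none. Guards against
# cycles by bounding the walk at the table size.
.ancestor_at <- function(taxid, taxonomy, rank) {
  idx <- match(taxid, taxonomy$taxid)
  steps <- 0L
  while (!is.na(idx)) {
    if (taxonomy$rank[idx] == rank) return(taxonomy$taxid[idx])
    steps <- steps + 1L
    if (steps > nrow(taxonomy)) stop("taxonomy error: cycle detected")
    idx <- match(taxonomy$parent[idx], taxonomy$taxid)
  }
  NA_character_
}

.taxon_name <- function(taxid, taxonomy) {
  taxonomy$name[match(taxid, taxonomy$taxid)]
}

#' Dereplicate annotated amplicons
#'
#' Merges byte-identical amplicon sequences, pooling their source taxa and
#' provenance. This is the step that turns a pile of per-accession in-silico
#' PCR hits into unique marker sequences with taxon sets.
#'
#' @param amplicons Data frame with columns `sequence` and `taxid`, and
#'   optionally `source` (an accession or record identifier; defaults to the
#'   row number).
#'
#' @return Data frame with one row per unique sequence: `sequence`,
#'   `taxids` (list column of unique source taxa), `n_sources`, and
#'   `sources` (list column of source identifiers).
#' @export
dereplicate_amplicons <- function(amplicons) {
  stopifnot(all(c("sequence", "taxid") %in% names(amplicons)))
  if (!nrow(amplicons))
    return(data.frame(sequence = character(0), n_sources = integer(0)))
  if (is.null(amplicons$source))
    amplicons$source <- as.character(seq_len(nrow(amplicons)))
  sp <- split(amplicons, amplicons$sequence)
  out <- data.frame(sequence = names(sp), stringsAsFactors = FALSE)
  out$taxids <- I(lapply(sp, function(d) unique(d$taxid)))
  out$n_sources <- vapply(sp, nrow, 0L)
  out$sources <- I(lapply(sp, function(d) d$source))
  rownames(out) <- NULL
  out
}

#' Curate dereplicated sequences into a reference database
#'
#' Resolves each unique marker sequence to a single curated taxon. A sequence
#' observed in one taxon keeps that taxon; a sequence shared by several
#' species of one genus is lifted to the genus; a sequence shared across
#' genera of one family becomes a combined multi-genus group named by its
#' member genera (e.g. `"Malus/Pyrus"`); sequences shared across families, or
#' not identifiable to genus level or better, are dropped with a warning. An
#' audit table records every reassignment (original taxa -> updated taxon).
#'
#' @param derep Output of [dereplicate_amplicons()].
#' @param taxonomy Taxonomy table (`taxid`, `name`, `rank`, `parent`).
#' @param length_bounds Inclusive amplicon length bounds retained in the
#'   database (default `c(9, 300)`).
#'
#' @return A `reference_db` object: list with `entries` (data frame
#'   `sequence`, `taxid`, `name`, `rank`), `taxonomy` (input table augmented
#'   with any multi-genus nodes), `audit`, `provenance`, `length_bounds`.
#' @export
curate_taxonomy <- function(derep, taxonomy, length_bounds = c(9L, 300L)) {
  .check_taxonomy(taxonomy)
  missing <- setdiff(unique(unlist(derep$taxids)), taxonomy$taxid)
  if (length(missing))
    stop("taxonomy error: unresolvable taxids: ",
         paste(missing, collapse = ", "))

  new_nodes <- list()
  entries <- vector("list", nrow(derep))
  audit <- vector("list", nrow(derep))
  dropped <- character(0)

  for (i in seq_len(nrow(derep))) {
    taxa <- derep$taxids[[i]]
    ranks <- taxonomy$rank[match(taxa, taxonomy$taxid)]
    # species/genus inputs are curatable; a multigenus node (from an earlier
    # curation pass) is already a valid curated taxon when it stands alone
    if (any(!ranks %in% c("species", "genus", "multigenus"))) {
      dropped <- c(dropped, derep$sequence[i])
      next
    }
    if (length(taxa) == 1L) {
      upd <- taxa
    } else {
      genera <- vapply(taxa, .ancestor_at, "", taxonomy = taxonomy,
                       rank = "genus")
      if (anyNA(genera)) {
        dropped <- c(dropped, derep$sequence[i])
        next
      }
      if (length(unique(genera)) == 1L) {
        upd <- unique(genera)
      } else {
        fams <- vapply(unique(genera), .ancestor_at, "",
                       taxonomy = taxonomy, rank = "family")
        if (anyNA(fams) || length(unique(fams)) > 1L) {
          dropped <- c(dropped, derep$sequence[i])
          next
        }
        gnames <- sort(.taxon_name(unique(genera), taxonomy))
        mg_name <- paste(gnames, collapse = "/")
        mg_id <- paste0("mg:", mg_name)
        if (is.null(new_nodes[[mg_id]]))
          new_nodes[[mg_id]] <- data.frame(
            taxid = mg_id, name = mg_name, rank = "multigenus",
            parent = unique(fams), stringsAsFactors = FALSE)
        upd <- mg_id
      }
    }
    entries[[i]] <- data.frame(sequence = derep$sequence[i], taxid = upd,
                               stringsAsFactors = FALSE)
    if (length(taxa) > 1L || upd != taxa[1]) {
      audit[[i]] <- data.frame(
        sequence = derep$sequence[i],
        original_taxids = paste(taxa, collapse = ";"),
        original_names = paste(.taxon_name(taxa, taxonomy), collapse = ";"),
        updated_taxid = upd, stringsAsFactors = FALSE)
    }
  }

  if (length(dropped))
    warning(length(dropped),
            " sequence(s) dropped: not identifiable at genus level or ",
            "better, or shared across families")

  taxonomy_out <- rbind(taxonomy[, c("taxid", "name", "rank", "parent")],
                        do.call(rbind, unname(new_nodes)))
  entries <- do.call(rbind, entries[!vapply(entries, is.null, TRUE)])
  if (is.null(entries))
    entries <- data.frame(sequence = character(0), taxid = character(0),
                          stringsAsFactors = FALSE)
  entries$name <- .taxon_name(entries$taxid, taxonomy_out)
  entries$rank <- taxonomy_out$rank[match(entries$taxid, taxonomy_out$taxid)]
  bad_len <- nchar(entries$sequence) < length_bounds[1] |
    nchar(entries$sequence) > length_bounds[2]
  entries <- entries[!bad_len, , drop = FALSE]
  rownames(entries) <- NULL
  audit <- do.call(rbind, audit[!vapply(audit, is.null, TRUE)])
  if (is.null(audit))
    audit <- data.frame(sequence = character(0), original_taxids = character(0),
                        original_names = character(0),
                        updated_taxid = character(0), stringsAsFactors = FALSE)
  audit$updated_name <- .taxon_name(audit$updated_taxid, taxonomy_out)
  keep <- match(entries$sequence, derep$sequence)
  provenance <- data.frame(
    sequence = entries$sequence,
    n_sources = derep$n_sources[keep],
    sources = vapply(derep$sources[keep], paste, "", collapse = ";"),
    stringsAsFactors = FALSE)

  structure(list(entries = entries, taxonomy = taxonomy_out, audit = audit,
                 provenance = provenance, length_bounds = length_bounds,
                 exclusions = character(0)),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("Curated P6 reference database\n")
  cat("  unique sequences:", nrow(x$entries), "\n")
  cat("  curated taxa:    ", length(unique(x$entries$taxid)), "\n")
  tab <- table(x$entries$rank[!duplicated(x$entries$taxid)])
  if (length(tab))
    cat("  taxon ranks:     ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (length(x$exclusions))
    cat("  exclusions:      ", paste(x$exclusions, collapse = ", "), "\n")
  invisible(x)
}

#' Exclude taxa from a reference database
#'
#' Removes database entries whose curated taxon is on the exclusion list
#' (matched by taxon name or taxid). The applied list is stored on the
#' returned database so that diary coding can apply the identical exclusions
#' and the two detection surfaces stay comparable.
#'
#' @param db A `reference_db`.
#' @param exclude Character vector of taxon names (or taxids) to exclude.
#' @return The filtered `reference_db`, with `$exclusions` updated.
#' @export
apply_exclusions <- function(db, exclude) {
  stopifnot(inherits(db, "reference_db"))
  if (!length(exclude)) return(db)
  known <- exclude %in% db$taxonomy$name | exclude %in% db$taxonomy$taxid
  if (any(!known))
    warning("exclusion name(s) not in taxonomy: ",
            paste(exclude[!known], collapse = ", "))
  drop <- db$entries$name %in% exclude | db$entries$taxid %in% exclude
  db$entries <- db$entries[!drop, , drop = FALSE]
  db$provenance <- db$provenance[db$provenance$sequence %in%
                                   db$entries$sequence, , drop = FALSE]
  db$exclusions <- union(db$exclusions, exclude)
  db
}

#' Build a curated P6 reference database from annotated sequences
#'
#' Runs the full database-construction path: in-silico PCR on every reference
#' record (both strands, mismatch-tolerant), dereplication of the recovered
#' amplicons, taxonomic curation of shared sequences, and optional taxon
#' exclusions.
#'
#' @param sequences Named character vector of reference nucleotide sequences
#'   (names are taxids, optionally followed by a description), a
#'   `DNAStringSet`, or the path to a FASTA file.
#' @param taxonomy Taxonomy table (`taxid`, `name`, `rank`, `parent`).
#' @param primers A [primer_pair()] (default [trnl_p6_primers()]).
#' @param max_mismatch Per-primer mismatch allowance for the reference search
#'   (default: the pair's `max_mismatch_db`, 4).
#' @param length_bounds Inclusive amplicon length bounds (default `c(9, 300)`).
#' @param exclude Taxon names to exclude after curation.
#'
#' @return A `reference_db` (see [curate_taxonomy()]).
#' @export
build_reference_db <- function(sequences, taxonomy,
                               primers = trnl_p6_primers(),
                               max_mismatch = primers$max_mismatch_db,
                               length_bounds = c(9L, 300L),
                               exclude = character(0)) {
  sequences <- .as_named_sequences(sequences)
  hits <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    amp <- insilico_pcr(sequences[[i]], primers, max_mismatch = max_mismatch,
                        length_bounds = length_bounds)
    if (nrow(amp)) {
      taxid <- sub("\\s.*$", "", names(sequences)[i])
      hits[[i]] <- data.frame(sequence = amp$amplicon, taxid = taxid,
                              source = names(sequences)[i],
                              stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  if (is.null(hits))
    stop("empty-reference error: no amplicon recovered from any record")
  db <- curate_taxonomy(dereplicate_amplicons(hits), taxonomy,
                        length_bounds = length_bounds)
  apply_exclusions(db, exclude)
}

# Accept a named character vector, DNAStringSet, or FASTA path.
.as_named_sequences <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet"))
    return(stats::setNames(as.character(sequences), names(sequences)))
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences) && !grepl("^[ACGTNacgtn]+$", sequences)) {
    x <- Biostrings::readDNAStringSet(sequences)
    return(stats::setNames(as.character(x), names(x)))
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("reference sequences must be named by taxid")
  toupper(sequences)
}

#' Write a curated reference database to disk
#'
#' Writes the curated FASTA (headers carry the curated taxid), the
#' reassignment audit TSV, the provenance TSV, and the augmented taxonomy TSV.
#'
#' @param db A `reference_db`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_reference_db <- function(db, dir) {
  stopifnot(inherits(db, "reference_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("%s seq%03d", db$entries$taxid, seq_len(nrow(db$entries)))
  fa <- Biostrings::DNAStringSet(stats::setNames(db$entries$sequence, ids))
  paths <- c(fasta = file.path(dir, "reference_db.fasta"),
             audit = file.path(dir, "reassignment_audit.tsv"),
             provenance = file.path(dir, "provenance.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"))
  Biostrings::writeXStringSet(fa, paths["fasta"])
  utils::write.table(db$audit, paths["audit"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(db$provenance, paths["provenance"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(db$taxonomy, paths["taxonomy"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}
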