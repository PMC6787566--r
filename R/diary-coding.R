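# Diet diaries arrive as one row per (participant, day, food_name). A
# lexicon maps food common names onto the curated taxon vocabulary so the
# diary and the sequencing data are compared on identical columns.

#' Build a diary lexicon
#'
#' @param mapping Data frame with columns `food_name` and `taxid` mapping
#'   each diary common name to a curated taxon. Several names may map to one
#'   taxon (combined with OR during coding).
#' @param exclude Character vector of food names contributing nothing (the
#'   same exclusion list applied to the reference database, so both sides of
#'   the comparison stay aligned).
#' @return A `lexicon` list.
#' @export
lexicon <- function(mapping, exclude = character(0)) {
  stopifnot(all(c("food_name", "taxid") %in% names(mapping)))
  if (!nrow(mapping)) stop("config error: empty lexicon")
  if (any(mapping$food_name %in% exclude))
    stop("lexicon targets and exclusions must be disjoint")
  structure(list(mapping = mapping[, c("food_name", "taxid")],
                 exclude = exclude), class = "lexicon")
}

#' Default common-name lexicon for frequently eaten plants
#'
#' Ships the combined-taxon conventions needed when several common names are
#' genetically one taxon at the P6 locus (e.g. broccoli, Brussels sprouts and
#' cabbage are all Brassica oleracea; apples and pears are indistinguishable
#' and share a combined Malus/Pyrus group; rice, rye and wheat collapse
#' within Poaceae) or when one common name spans several genera ("berries",
#' "beans"). Cranberry and generic spices are excluded. The table is plain
#' text under `inst/extdata/default_lexicon.tsv` and is meant to be edited.
#'
#' @return A `lexicon`.
#' @export
default_lexicon <- function() {
  path <- system.file("extdata", "default_lexicon.tsv",
                      package = "dietbarcode", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lexicon(tab[!tab$excluded, c("food_name", "taxid")],
          exclude = tab$food_name[tab$excluded])
}

#' Code diary entries onto the curated taxon vocabulary
#'
#' Maps each diary food name through the lexicon and returns the set of taxa
#' reported per (participant, day). Names mapping to the same taxon combine
#' by boolean OR; excluded names contribute nothing; unknown names are
#' collected into an `uncoded` report rather than silently dropped.
#'
#' @param entries Data frame with columns `participant`, `day`, `food_name`.
#' @param lex A [lexicon()].
#' @return List with `presence` (data frame `participant`, `day`, `taxid`,
#'   unique rows) and `uncoded` (data frame of unknown names with counts).
#' @export
code_diary <- function(entries, lex) {
  stopifnot(inherits(lex, "lexicon"),
            all(c("participant", "day", "food_name") %in% names(entries)))
  excluded <- entries$food_name %in% lex$exclude
  idx <- match(entries$food_name, lex$mapping$food_name)
  unknown <- is.na(idx) & !excluded
  uncoded <- if (any(unknown)) {
    tab <- table(entries$food_name[unknown])
    data.frame(food_name = names(tab), n_entries = as.integer(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(food_name = character(0), n_entries = integer(0))
  ok <- !is.na(idx) & !excluded
  presence <- unique(data.frame(participant = entries$participant[ok],
                                day = entries$day[ok],
                                taxid = lex$mapping$taxid[idx[ok]],
                                stringsAsFactors = FALSE))
  presence <- presence[order(presence$participant, presence$day,
                             presence$taxid), , drop = FALSE]
  rownames(presence) <- NULL
  list(presence = presence, uncoded = uncoded)
}

#' Pair diary days to stool samples (day-prior rule)
#'
#' A stool sample collected on day d is paired with the diary of day d - 1
#' for the same participant; samples lacking a day-prior diary entry set are
#' dropped with a warning. Returns the samples x taxa logical diary matrix on
#' a fixed taxon vocabulary.
#'
#' @param presence `presence` frame from [code_diary()].
#' @param metadata Sample metadata: data frame with `sample_id`,
#'   `participant`, `day` (collection day).
#' @param taxa Character vector fixing the column vocabulary (use the count
#'   table's taxa so both matrices align). Defaults to the taxa observed in
#'   `presence`.
#' @param diary_days Optional data frame (`participant`, `day`) listing every
#'   day a diary was kept, so that a day with no plant entries still counts
#'   as an observed (all-FALSE) diary day. Defaults to the days present in
#'   `presence`.
#' @return Logical matrix samples x taxa with attribute `pairing` (data frame
#'   `sample_id`, `participant`, `diary_day`) and `dropped` (sample ids
#'   lacking a day-prior diary).
#' @export
pair_to_samples <- function(presence, metadata, taxa = NULL,
                            diary_days = NULL) {
  stopifnot(all(c("sample_id", "participant", "day") %in% names(metadata)))
  if (anyDuplicated(metadata[, c("participant", "day")]))
    stop("data error: duplicate (participant, day) stool entries")
  if (is.null(taxa)) taxa <- sort(unique(presence$taxid))
  if (is.null(diary_days))
    diary_days <- unique(presence[, c("participant", "day")])
  key <- function(p, d) paste(p, d, sep = "\r")
  have_diary <- key(metadata$participant, metadata$day - 1) %in%
    key(diary_days$participant, diary_days$day)
  if (any(!have_diary))
    warning("dropping ", sum(!have_diary),
            " sample(s) without a day-prior diary: ",
            paste(metadata$sample_id[!have_diary], collapse = ", "))
  meta <- metadata[have_diary, , drop = FALSE]
  mat <- matrix(FALSE, nrow = nrow(meta), ncol = length(taxa),
                dimnames = list(meta$sample_id, taxa))
  hit <- match(key(presence$participant, presence$day + 1),
               key(meta$participant, meta$day))
  ok <- !is.na(hit) & presence$taxid %in% taxa
  mat[cbind(hit[ok], match(presence$taxid[ok], taxa))] <- TRUE
  attr(mat, "pairing") <- data.frame(sample_id = meta$sample_id,
                                     participant = meta$participant,
                                     diary_day = meta$day - 1,
                                     stringsAsFactors = FALSE)
  attr(mat, "dropped") <- metadata$sample_id[!have_diary]
  mat
}
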