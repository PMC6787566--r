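# End-to-end orchestration: simulate (or load) a study, build the reference
# database, process reads, code the diary, and evaluate concordance and
# community statistics. Each stage contributes a manifest entry (inputs,
# parameters, counts in/out) so reruns are auditable; identical config and
# seed reproduce identical tables.

#' Derive a diary lexicon from a simulated study's curated database
#'
#' Maps each simulated species' diary food name to the curated taxon its P6
#' sequence resolves to in the database. Species whose sequence was dropped
#' during curation or excluded are placed on the exclusion list so that the
#' diary and the sequencing data keep identical vocabularies.
#'
#' @param reference Output of [simulate_reference()].
#' @param db A `reference_db` built from that reference.
#' @return A [lexicon()].
#' @export
study_lexicon <- function(reference, db) {
  hit <- match(reference$p6, db$entries$sequence)
  food <- unname(reference$common_names[names(reference$p6)])
  mapping <- data.frame(food_name = food[!is.na(hit)],
                        taxid = db$entries$taxid[hit[!is.na(hit)]],
                        stringsAsFactors = FALSE)
  lexicon(mapping, exclude = food[is.na(hit)])
}

#' Run the complete benchmarking pipeline on a simulated study
#'
#' Executes every stage in order: simulate the study, build the curated
#' reference database by in-silico PCR, process the reads into a count
#' table, code the diary onto the curated vocabulary with day-prior pairing,
#' and evaluate the concordance grid, Venn partition, per-taxon error rates,
#' and (optionally) period-wise Mantel tests. Rerunning with the same
#' configuration reproduces identical tables.
#'
#' @param config A [study_config()].
#' @param primers A [primer_pair()].
#' @param params A [filter_params()].
#' @param levels,thresholds Grid axes passed to [metric_grid()].
#' @param exclude Taxon names excluded from both the database and the diary.
#' @param run_stats Evaluate period-wise Mantel tests (default TRUE).
#' @return A `study_run` list: `sim`, `db`, `run` (the
#'   `metabarcoding_run`), `diary`, `grid`, `venn`, `error_rates`,
#'   `mantel` (or NULL), `manifest`.
#' @export
run_study_pipeline <- function(config = study_config(),
                               primers = trnl_p6_primers(),
                               params = filter_params(),
                               levels = c("all", "species", "genus", "family"),
                               thresholds = c(0, 0.01, 0.05),
                               exclude = character(0),
                               run_stats = TRUE) {
  manifest <- list()
  sim <- simulate_study(config, primers)
  manifest$simulate <- list(seed = config$seed, n_reads = nrow(sim$reads),
                            n_samples = nrow(sim$truth$metadata))

  db <- build_reference_db(sim$reference$fasta, sim$reference$taxonomy,
                           primers, exclude = exclude)
  manifest$build_db <- list(n_entries = nrow(db$entries),
                            n_taxa = length(unique(db$entries$taxid)),
                            exclusions = db$exclusions)

  run <- process_reads(sim$reads, sim$mid_map, db, primers, params)
  manifest$process_reads <- as.list(run$conservation)

  lex <- study_lexicon(sim$reference, db)
  coded <- code_diary(sim$truth$diary_entries, lex)
  diary <- pair_to_samples(coded$presence, sim$truth$metadata,
                           taxa = colnames(run$counts),
                           diary_days = sim$truth$diary_days)
  manifest$code_diary <- list(n_entries = nrow(sim$truth$diary_entries),
                              n_uncoded = nrow(coded$uncoded),
                              n_paired = nrow(diary))

  subsets <- list(
    `all samples` = rownames(run$counts),
    `plant arm` = sim$truth$metadata$sample_id[
      sim$truth$metadata$period_type == "plant"])
  grid <- metric_grid(run$counts, diary, db$taxonomy, subsets = subsets,
                      levels = levels, thresholds = thresholds)
  det <- detect_presence(run$counts, 0)
  common <- intersect(rownames(det), rownames(diary))
  venn <- venn_partition(det[common, , drop = FALSE],
                         diary[common, , drop = FALSE])
  err <- taxon_error_rates(det, diary)
  manifest$concord <- list(n_grid_rows = nrow(grid))

  mant <- NULL
  if (run_stats) {
    mant <- suppressWarnings(
      periodwise_mantel(run$counts, diary, sim$truth$metadata,
                        periods = unique(sim$truth$metadata$period),
                        permutations = 999, seed = config$seed))
    manifest$stats <- list(n_periods_tested = NROW(mant))
  }

  structure(list(sim = sim, db = db, run = run, diary = diary, grid = grid,
                 venn = venn, error_rates = err, mantel = mant,
                 manifest = manifest),
            class = "study_run")
}

#' @export
print.study_run <- function(x, ...) {
  cat("Simulated feeding-study benchmark\n")
  cat("  samples sequenced:", nrow(x$run$counts),
      "| taxa in db:", length(unique(x$db$entries$taxid)), "\n")
  top <- x$grid[x$grid$subset == "all samples" & x$grid$level == "all" &
                  x$grid$threshold == 0, ]
  if (nrow(top))
    cat(sprintf("  all/all/>0%%: recall=%.2f precision=%.2f F=%.2f\n",
                top$recall, top$precision, top$fmeasure))
  invisible(x)
}

#' Write a packaged synthetic dataset
#'
#' Generates and writes a self-contained simulated study (reference,
#' taxonomy, reads, MID map, diary, metadata, truth tables) at one of two
#' scales: `"tiny"` (3 participants, 4 taxa, shallow reads; completes in
#' seconds) or `"small"` (the full 11-participant design over 45 taxa).
#'
#' @param scale `"tiny"` or `"small"`.
#' @param dir Output directory.
#' @param seed RNG seed.
#' @return Invisibly, the list of paths written (see [write_study()]).
#' @export
make_fixtures <- function(scale = c("tiny", "small"), dir, seed = 1L) {
  scale <- match.arg(scale)
  config <- switch(scale,
    tiny = study_config(
      n_participants = 3L,
      periods = data.frame(label = c("baseline", "plant", "washout"),
                           type = c("free", "plant", "free"),
                           days = c(2L, 2L, 2L), stringsAsFactors = FALSE),
      n_plant_taxa = 4L, shared_sequence_groups = list(),
      non_amplifying_taxa = integer(0), amplification_failure_prob = 0,
      reads_per_sample = 200, plant_menu_size = 2L, mean_taxa_free = 2,
      seed = seed),
    small = study_config(seed = seed))
  sim <- simulate_study(config)
  invisible(write_study(sim, dir))
}
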