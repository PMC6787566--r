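# Synthetic controlled-feeding study with known ground truth. The generator
# emulates the design used in short-term diet-intervention work: a cohort
# eats freely at baseline, then a controlled plant-based arm, a washout, a
# second baseline, a controlled animal-based arm (nearly plant-free), and a
# final washout, keeping daily diet diaries throughout while stool is
# collected and amplicon-sequenced. Intake on day d reaches the stool sample
# of day d + 1 (the day-prior pairing rule is built into truth generation).

#' Configuration of a simulated feeding study
#'
#' All downstream stages are exercisable from this single object; the seed
#' fixes every output bit-for-bit.
#'
#' @param n_participants Cohort size (default 11).
#' @param periods Data frame `label`, `type` (`"free"`, `"plant"`,
#'   `"animal"`), `days`; defaults to baseline 4 d, plant arm 5 d, washout
#'   6 d, baseline 4 d, animal arm 5 d, washout 6 d.
#' @param n_plant_taxa Number of reference plant species (default 45).
#' @param shared_sequence_groups List of integer vectors: taxa (by index)
#'   sharing one byte-identical P6 haplotype, e.g. an apple/pear-like pair.
#'   Groups must be disjoint.
#' @param diary_omission_prob Probability that a truly eaten taxon is absent
#'   from the diary (memory lapse / selective reporting).
#' @param trace_ingredient_prob Probability a consumed taxon is a hidden
#'   ingredient the participant never diaries (processed foods).
#' @param non_amplifying_taxa Taxon indices whose DNA never yields reads
#'   (coffee-like heavily processed foods).
#' @param amplification_failure_prob Probability a stool sample yields no
#'   reads at all (default 0.5).
#' @param reads_per_sample Mean read depth per amplified sample (Poisson).
#' @param abundance_skew Log-normal sdlog of within-sample relative
#'   abundances (skew of the dietary proportions).
#' @param per_base_error_rate Per-base substitution probability in reads.
#' @param quality_mean Mean Phred score of simulated base qualities.
#' @param seed Integer RNG seed.
#' @param plant_menu_size,animal_menu_size Number of plant taxa on the
#'   controlled plant-arm menu (default: 12 or all amplifiable taxa,
#'   whichever is fewer) and residual plant taxa allowed on the animal arm
#'   (default 1, a tea-like beverage).
#' @param mean_taxa_free Mean number of plant taxa eaten per free-eating day.
#' @param menu_item_prob Daily probability of eating each plant-arm menu item.
#' @return A `study_config` list.
#' @export
study_config <- function(n_participants = 11L,
                         periods = NULL,
                         n_plant_taxa = 45L,
                         shared_sequence_groups = list(c(1L, 2L),
                                                       c(3L, 4L, 5L)),
                         diary_omission_prob = 0.1,
                         trace_ingredient_prob = 0.05,
                         non_amplifying_taxa = 6L,
                         amplification_failure_prob = 0.5,
                         reads_per_sample = 2000,
                         abundance_skew = 1.5,
                         per_base_error_rate = 0.002,
                         quality_mean = 36,
                         seed = 1L,
                         plant_menu_size = NULL,
                         animal_menu_size = 1L,
                         mean_taxa_free = 8,
                         menu_item_prob = 0.5) {
  if (is.null(periods))
    periods <- data.frame(
      label = c("baseline1", "plant", "washout1", "baseline2", "animal",
                "washout2"),
      type = c("free", "plant", "free", "free", "animal", "free"),
      days = c(4L, 5L, 6L, 4L, 5L, 6L),
      stringsAsFactors = FALSE)
  if (n_plant_taxa < 2) stop("invalid-config error: need >= 2 plant taxa")
  if (is.null(plant_menu_size))
    plant_menu_size <- min(12L, n_plant_taxa - length(non_amplifying_taxa))
  probs <- c(diary_omission_prob, trace_ingredient_prob,
             amplification_failure_prob, per_base_error_rate, menu_item_prob)
  if (any(probs < 0 | probs > 1))
    stop("invalid-config error: probabilities must lie in [0, 1]")
  if (any(periods$days < 1))
    stop("invalid-config error: period lengths must be >= 1")
  if (!all(periods$type %in% c("free", "plant", "animal")))
    stop("invalid-config error: period type must be free/plant/animal")
  shared <- unlist(shared_sequence_groups)
  if (length(shared) != length(unique(shared)))
    stop("invalid-config error: shared-sequence groups must be disjoint")
  if (length(shared) > n_plant_taxa ||
      (length(shared) && max(shared) > n_plant_taxa))
    stop("invalid-config error: shared groups exceed available taxa")
  if (length(non_amplifying_taxa) &&
      max(non_amplifying_taxa) > n_plant_taxa)
    stop("invalid-config error: non-amplifying index exceeds taxa")
  if (any(periods$type == "plant") && plant_menu_size < 1)
    stop("invalid-config error: empty plant menu for a plant period")
  if (plant_menu_size > n_plant_taxa - length(non_amplifying_taxa))
    stop("invalid-config error: plant menu larger than amplifiable taxa")
  structure(list(n_participants = as.integer(n_participants),
                 periods = periods,
                 n_plant_taxa = as.integer(n_plant_taxa),
                 shared_sequence_groups = lapply(shared_sequence_groups,
                                                 as.integer),
                 diary_omission_prob = diary_omission_prob,
                 trace_ingredient_prob = trace_ingredient_prob,
                 non_amplifying_taxa = as.integer(non_amplifying_taxa),
                 amplification_failure_prob = amplification_failure_prob,
                 reads_per_sample = reads_per_sample,
                 abundance_skew = abundance_skew,
                 per_base_error_rate = per_base_error_rate,
                 quality_mean = quality_mean,
                 seed = as.integer(seed),
                 plant_menu_size = as.integer(plant_menu_size),
                 animal_menu_size = as.integer(animal_menu_size),
                 mean_taxa_free = mean_taxa_free,
                 menu_item_prob = menu_item_prob),
            class = "study_config")
}

.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

#' Simulate reference plant sequences and their taxonomy
#'
#' Generates one reference record per plant species: a random P6 insert
#' flanked by the study primer binding sites and short random flanks. Species
#' in one shared-sequence group receive byte-identical P6 inserts (and are
#' placed in one family, in distinct genera, so curation collapses them into
#' a multi-genus group); all other inserts are pairwise distinct. Species are
#' organised three genera to a family.
#'
#' @param config A [study_config()].
#' @param primers A [primer_pair()] (default [trnl_p6_primers()]).
#' @return List with `fasta` (named reference sequences, names
#'   `"<taxid> <species name>"`), `taxonomy` (taxid/name/rank/parent),
#'   `p6` (named P6 inserts per species taxid), `common_names` (diary food
#'   name per species taxid), `primers`.
#' @export
simulate_reference <- function(config, primers = trnl_p6_primers()) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  n <- config$n_plant_taxa
  fam_of <- ceiling(seq_len(n) / 3)
  for (grp in config$shared_sequence_groups)
    fam_of[grp] <- fam_of[grp[1]]
  fams <- sort(unique(fam_of))
  taxonomy <- rbind(
    data.frame(taxid = sprintf("f_%02d", fams),
               name = sprintf("Family%02d", fams),
               rank = "family", parent = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(taxid = sprintf("g_%02d", seq_len(n)),
               name = sprintf("Genus%02d", seq_len(n)),
               rank = "genus", parent = sprintf("f_%02d", fam_of),
               stringsAsFactors = FALSE),
    data.frame(taxid = sprintf("sp_%02d", seq_len(n)),
               name = sprintf("Genus%02d specius", seq_len(n)),
               rank = "species", parent = sprintf("g_%02d", seq_len(n)),
               stringsAsFactors = FALSE))

  # one representative insert per shared group, one per remaining species
  group_of <- seq_len(n)
  for (k in seq_along(config$shared_sequence_groups))
    group_of[config$shared_sequence_groups[[k]]] <- n + k
  reps <- unique(group_of)
  repeat {
    lens <- sample(25:90, length(reps), replace = TRUE)
    rep_seq <- vapply(seq_along(reps), function(i) .random_dna(1, lens[i]), "")
    if (!anyDuplicated(rep_seq)) break
  }
  p6 <- rep_seq[match(group_of, reps)]
  names(p6) <- sprintf("sp_%02d", seq_len(n))

  flank5 <- .random_dna(n, 10)
  flank3 <- .random_dna(n, 10)
  fasta <- paste0(flank5, primers$forward, p6, revcomp(primers$reverse),
                  flank3)
  names(fasta) <- sprintf("sp_%02d Genus%02d specius", seq_len(n), seq_len(n))
  common <- stats::setNames(sprintf("food_%02d", seq_len(n)), names(p6))
  list(fasta = fasta, taxonomy = taxonomy, p6 = p6, common_names = common,
       primers = primers)
}

#' Simulate intake, diaries, and amplification ground truth
#'
#' Draws daily plant intake per participant (free eating from the whole
#' taxon pool; the plant arm from a fixed controlled menu; the animal arm
#' from a near-empty residual plant set, allowing zero-plant days), assigns
#' skewed within-sample relative abundances, marks trace ingredients (never
#' diaried) and independent diary omissions, and decides per-sample
#' amplification success. Intake on day d is attributed to the stool sample
#' of day d + 1.
#'
#' @param config A [study_config()].
#' @param reference Output of [simulate_reference()].
#' @return A `ground_truth` list: `true_intake` and `diary_matrix` (logical
#'   samples x taxa), `true_proportions` (rows sum to 1 over consumed taxa),
#'   `amplified` (named logical), `metadata` (`sample_id`, `participant`,
#'   `day`, `period`, `period_type`), `diary_entries` (`participant`, `day`,
#'   `food_name`, `period`), `diary_days`, `menus`.
#' @export
simulate_feeding <- function(config, reference) {
  stopifnot(inherits(config, "study_config"))
  taxa <- names(reference$p6)
  n_taxa <- length(taxa)
  if (n_taxa < config$n_plant_taxa)
    stop("reference has fewer taxa than the configuration requests")
  set.seed(config$seed + 1L)

  amplifiable <- setdiff(seq_len(n_taxa), config$non_amplifying_taxa)
  plant_menu <- sort(sample(amplifiable, config$plant_menu_size))
  animal_pool <- setdiff(seq_len(n_taxa), plant_menu)
  animal_menu <- if (config$animal_menu_size > 0)
    sort(sample(animal_pool, min(config$animal_menu_size,
                                 length(animal_pool)))) else integer(0)

  day_type <- rep(config$periods$type, config$periods$days)
  day_label <- rep(config$periods$label, config$periods$days)
  n_days <- length(day_type)
  p_free <- min(1, config$mean_taxa_free / n_taxa)

  n_samples <- config$n_participants * n_days
  ids <- character(n_samples)
  meta <- vector("list", n_samples)
  intake <- matrix(FALSE, n_samples, n_taxa)
  row <- 0L
  for (p in seq_len(config$n_participants)) {
    for (d in seq_len(n_days)) {
      row <- row + 1L
      eaten <- switch(day_type[d],
        free = which(stats::runif(n_taxa) < p_free),
        plant = plant_menu[stats::runif(length(plant_menu)) <
                             config$menu_item_prob],
        animal = animal_menu[stats::runif(length(animal_menu)) < 0.3])
      intake[row, eaten] <- TRUE
      ids[row] <- sprintf("P%02d_D%02d", p, d + 1L)
      meta[[row]] <- data.frame(sample_id = ids[row], participant = p,
                                day = d + 1L, period = day_label[d],
                                period_type = day_type[d],
                                stringsAsFactors = FALSE)
    }
  }
  dimnames(intake) <- list(ids, taxa)
  metadata <- do.call(rbind, meta)

  props <- matrix(0, n_samples, n_taxa, dimnames = dimnames(intake))
  for (i in seq_len(n_samples)) {
    k <- sum(intake[i, ])
    if (k > 0) {
      w <- stats::rlnorm(k, meanlog = 0, sdlog = config$abundance_skew)
      props[i, intake[i, ]] <- w / sum(w)
    }
  }

  trace <- intake & matrix(stats::runif(n_samples * n_taxa) <
                             config$trace_ingredient_prob,
                           n_samples, n_taxa)
  omitted <- matrix(stats::runif(n_samples * n_taxa) <
                      config$diary_omission_prob, n_samples, n_taxa)
  diary <- intake & !trace & !omitted
  amplified <- stats::setNames(
    stats::runif(n_samples) >= config$amplification_failure_prob, ids)

  diary_idx <- which(diary, arr.ind = TRUE)
  diary_entries <- data.frame(
    participant = metadata$participant[diary_idx[, 1]],
    day = metadata$day[diary_idx[, 1]] - 1L,
    food_name = unname(reference$common_names[taxa[diary_idx[, 2]]]),
    period = metadata$period[diary_idx[, 1]],
    stringsAsFactors = FALSE)
  diary_entries <- diary_entries[order(diary_entries$participant,
                                       diary_entries$day,
                                       diary_entries$food_name), ,
                                 drop = FALSE]
  rownames(diary_entries) <- NULL
  diary_days <- unique(data.frame(participant = metadata$participant,
                                  day = metadata$day - 1L))

  structure(list(true_intake = intake, true_proportions = props,
                 diary_matrix = diary, trace = trace, amplified = amplified,
                 metadata = metadata, diary_entries = diary_entries,
                 diary_days = diary_days,
                 menus = list(plant = taxa[plant_menu],
                              animal = taxa[animal_menu])),
            class = "ground_truth")
}

# Substitution errors at `rate` over a set of identical constructs.
.mutate_reads <- function(construct, k, rate) {
  chars <- strsplit(construct, "")[[1]]
  L <- length(chars)
  m <- matrix(rep(chars, each = k), nrow = k)
  err <- matrix(stats::runif(k * L) < rate, nrow = k)
  if (any(err)) {
    idx <- which(err)
    orig <- m[idx]
    repl <- vapply(orig, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    m[idx] <- repl
  }
  apply(m, 1, paste, collapse = "")
}

#' Simulate MID-tagged amplicon reads with sequencing errors
#'
#' For each amplified stool sample, draws a Poisson read depth around
#' `reads_per_sample`, partitions it multinomially over the sample's
#' amplifiable consumed taxa according to the true proportions, and emits
#' primer-P6-primer constructs carrying the sample's MID tag, per-base
#' substitution errors downstream of the tag, and Phred qualities around
#' `quality_mean` (Phred+33). Non-amplifying taxa emit no reads; failed
#' samples emit none at all.
#'
#' @param config A [study_config()].
#' @param truth Output of [simulate_feeding()].
#' @param reference Output of [simulate_reference()].
#' @return List with `reads` (data frame `read_id`, `sequence`, `quality`)
#'   and `mid_map` (`mid`, `sample_id`, covering every sample).
#' @export
simulate_reads <- function(config, truth, reference) {
  stopifnot(inherits(config, "study_config"), inherits(truth, "ground_truth"))
  taxa <- colnames(truth$true_intake)
  unknown <- setdiff(taxa, names(reference$p6))
  if (length(unknown))
    stop("consistency error: truth references unknown taxa: ",
         paste(unknown, collapse = ", "))
  set.seed(config$seed + 2L)
  primers <- reference$primers
  samples <- rownames(truth$true_intake)

  repeat {
    mids <- .random_dna(length(samples), 8)
    if (!anyDuplicated(mids)) break
  }
  mid_map <- data.frame(mid = mids, sample_id = samples,
                        stringsAsFactors = FALSE)

  amp_ok <- !taxa %in% taxa[config$non_amplifying_taxa]
  out <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    if (!truth$amplified[i]) next
    props <- truth$true_proportions[i, ] * (amp_ok)
    if (sum(props) == 0) next
    props <- props / sum(props)
    depth <- stats::rpois(1, config$reads_per_sample)
    if (depth == 0) next
    counts <- as.integer(stats::rmultinom(1, depth, props))
    seqs <- character(depth)
    pos <- 0L
    for (t in which(counts > 0)) {
      construct <- paste0(primers$forward, reference$p6[[taxa[t]]],
                          revcomp(primers$reverse))
      k <- counts[t]
      seqs[pos + seq_len(k)] <- if (config$per_base_error_rate > 0)
        .mutate_reads(construct, k, config$per_base_error_rate)
      else rep(construct, k)
      pos <- pos + k
    }
    full <- paste0(mids[i], seqs)
    quals <- vapply(nchar(full), function(L) {
      q <- as.integer(round(stats::rnorm(L, config$quality_mean, 3)))
      intToUtf8(pmin(40L, pmax(2L, q)) + 33L)
    }, "")
    out[[i]] <- data.frame(
      read_id = sprintf("%s_r%05d", samples[i], seq_len(depth)),
      sequence = full, quality = quals, stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(reads))
    reads <- data.frame(read_id = character(0), sequence = character(0),
                        quality = character(0))
  rownames(reads) <- NULL
  list(reads = reads, mid_map = mid_map)
}

#' Simulate a complete feeding study
#'
#' Runs [simulate_reference()], [simulate_feeding()], and [simulate_reads()]
#' under one configuration.
#'
#' @param config A [study_config()].
#' @param primers A [primer_pair()].
#' @return List `config`, `reference`, `truth`, `reads`, `mid_map`.
#' @export
simulate_study <- function(config = study_config(),
                           primers = trnl_p6_primers()) {
  reference <- simulate_reference(config, primers)
  truth <- simulate_feeding(config, reference)
  rd <- simulate_reads(config, truth, reference)
  list(config = config, reference = reference, truth = truth,
       reads = rd$reads, mid_map = rd$mid_map)
}

#' Write a simulated study to disk as plain-text files
#'
#' Writes the reference FASTA, taxonomy TSV, reads FASTQ (Phred+33), MID map
#' TSV, diary TSV, sample metadata TSV, and the truth tables.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory.
#' @return Invisibly, the named vector of paths written.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reference = file.path(dir, "reference.fasta"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             reads = file.path(dir, "reads.fastq"),
             mids = file.path(dir, "mid_map.tsv"),
             diary = file.path(dir, "diary.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             true_intake = file.path(dir, "truth_intake.tsv"),
             true_proportions = file.path(dir, "truth_proportions.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$reference$fasta), paths["reference"])
  utils::write.table(sim$reference$taxonomy, paths["taxonomy"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_fastq(sim$reads, paths["reads"])
  utils::write.table(sim$mid_map, paths["mids"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth$diary_entries, paths["diary"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth$metadata, paths["metadata"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(sample_id = rownames(sim$truth$true_intake),
                                sim$truth$true_intake * 1L),
                     paths["true_intake"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(data.frame(sample_id = rownames(sim$truth$true_proportions),
                                sim$truth$true_proportions),
                     paths["true_proportions"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
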