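# Independent oracles and small fixture factories. The oracles deliberately
# avoid the package's implementation paths: naive per-position character
# loops, per-cell tallies, and explicit permutation enumeration.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
           R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
           B = "V", V = "B", D = "H", H = "D")
  paste(rev(map[strsplit(x, "")[[1]]]), collapse = "")
}

# Mismatches between a template window and a primer, one character at a time.
oracle_mismatches <- function(site, primer) {
  sc <- strsplit(site, "")[[1]]
  pc <- strsplit(primer, "")[[1]]
  mm <- 0L
  for (k in seq_along(pc)) {
    allowed <- ORACLE_IUPAC[[pc[k]]]
    if (is.null(allowed) || !(sc[k] %in% allowed)) mm <- mm + 1L
  }
  mm
}

# Exhaustive position-pair in-silico PCR: every (forward start, reverse-site
# start) pair on both strands, checked by brute force.
oracle_pcr <- function(template, fwd, rev, max_mm, bounds) {
  n <- nchar(template)
  rows <- list()
  scan <- function(s, strand) {
    rc_rev <- oracle_revcomp(rev)
    Lf <- nchar(fwd); Lr <- nchar(rc_rev)
    f_pos <- integer(0)
    for (i in seq_len(max(0, n - Lf + 1)))
      if (oracle_mismatches(substr(s, i, i + Lf - 1), fwd) <= max_mm)
        f_pos <- c(f_pos, i)
    r_pos <- integer(0)
    for (i in seq_len(max(0, n - Lr + 1)))
      if (oracle_mismatches(substr(s, i, i + Lr - 1), rc_rev) <= max_mm)
        r_pos <- c(r_pos, i)
    for (f in f_pos) {
      fe <- f + Lf - 1
      for (r in r_pos) {
        len <- r - fe - 1
        if (r > fe && len >= bounds[1] && len <= bounds[2]) {
          s0 <- fe; e0 <- r - 1
          if (strand == "-") { tmp <- n - e0; e0 <- n - s0; s0 <- tmp }
          rows[[length(rows) + 1]] <<- data.frame(
            amplicon = substr(s, fe + 1, r - 1), start = s0, end = e0,
            strand = strand, length = len, stringsAsFactors = FALSE)
        }
      }
    }
  }
  scan(template, "+")
  scan(oracle_revcomp(template), "-")
  if (!length(rows))
    return(data.frame(amplicon = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      length = integer(0)))
  do.call(rbind, rows)
}

# Canonical ordering so oracle and implementation outputs are comparable.
sort_amplicons <- function(df) {
  df <- df[order(df$strand, df$start, df$end, df$amplicon), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Random template with mutated primer-site insertions, for oracle testing.
random_template <- function(len, primers, n_inserts = 2, mutations = 0:3) {
  base <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = "")
  mutate <- function(s, k) {
    if (k == 0) return(s)
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), min(k, length(ch)))
    for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  for (i in seq_len(n_inserts)) {
    amp_len <- sample(c(5:15, 20:60), 1)
    cassette <- paste0(
      mutate(primers$forward, sample(mutations, 1)),
      paste(sample(c("A", "C", "G", "T"), amp_len, replace = TRUE),
            collapse = ""),
      mutate(oracle_revcomp(primers$reverse), sample(mutations, 1)))
    at <- sample(nchar(base) - 1, 1)
    base <- paste0(substr(base, 1, at), cassette,
                   substr(base, at + 1, nchar(base)))
  }
  base
}

# Per-cell tally of concordance counts, independent of the pooled path.
oracle_tally <- function(det, diary) {
  tp <- fp <- fn <- 0L
  for (i in seq_len(nrow(det))) {
    for (j in seq_len(ncol(det))) {
      if (det[i, j] && diary[i, j]) tp <- tp + 1L
      else if (det[i, j]) fp <- fp + 1L
      else if (diary[i, j]) fn <- fn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn)
}

# All permutations of 1:n as a matrix (n small).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
    out <- rbind(out, block)
  }
  out
}

# A small ideal study configuration: no noise, omissions, failures, shared
# haplotypes, or non-amplifying taxa, so the pipeline must recover truth.
ideal_config <- function(seed = 42L, n_participants = 3L, days = c(2L, 2L, 2L),
                         n_taxa = 6L, reads = 300, ...) {
  study_config(
    n_participants = n_participants,
    periods = data.frame(label = c("baseline", "plant", "washout"),
                         type = c("free", "plant", "free"), days = days,
                         stringsAsFactors = FALSE),
    n_plant_taxa = n_taxa, shared_sequence_groups = list(),
    non_amplifying_taxa = integer(0), diary_omission_prob = 0,
    trace_ingredient_prob = 0, amplification_failure_prob = 0,
    per_base_error_rate = 0, reads_per_sample = reads, abundance_skew = 0.8,
    plant_menu_size = min(3L, n_taxa), mean_taxa_free = 2, seed = seed, ...)
}

# Hand-built two-taxon taxonomy for curation tests.
toy_taxonomy <- function() {
  data.frame(
    taxid = c("f_rosaceae", "f_poaceae", "f_fabaceae",
               "g_malus", "g_pyrus", "g_oryza", "g_secale", "g_triticum",
               "g_phaseolus",
               "sp_malus", "sp_pyrus", "sp_rice", "sp_rye", "sp_wheat",
               "sp_pvulgaris", "sp_plunatus"),
    name = c("Rosaceae", "Poaceae", "Fabaceae",
             "Malus", "Pyrus", "Oryza", "Secale", "Triticum", "Phaseolus",
             "Malus domestica", "Pyrus communis", "Oryza sativa",
             "Secale cereale", "Triticum aestivum", "Phaseolus vulgaris",
             "Phaseolus lunatus"),
    rank = c(rep("family", 3), rep("genus", 6), rep("species", 7)),
    parent = c(NA, NA, NA,
               "f_rosaceae", "f_rosaceae", "f_poaceae", "f_poaceae",
               "f_poaceae", "f_fabaceae",
               "g_malus", "g_pyrus", "g_oryza", "g_secale", "g_triticum",
               "g_phaseolus", "g_phaseolus"),
    stringsAsFactors = FALSE)
}
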