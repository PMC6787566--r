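test_that("f_measure is the harmonic mean with defined boundary cases", {
  expect_equal(f_measure(1, 1), 1)
  expect_equal(f_measure(0, 0), 0)
  expect_equal(f_measure(0.5, 0.5), 0.5)
  expect_equal(f_measure(0.30, 0.90), 0.45)
  expect_error(f_measure(1.2, 0.5), "domain")
  expect_error(f_measure(0.5, -0.1), "domain")
  # tends toward the lesser value: F <= arithmetic mean
  set.seed(5)
  r <- runif(50); p <- runif(50)
  expect_true(all(f_measure(r, p) <= (r + p) / 2 + 1e-12))
  expect_true(all(f_measure(r, p) <= 2 * pmin(r, p) + 1e-12))
})

test_that("detection threshold is a strict relative-abundance inequality", {
  m <- matrix(c(99L, 1L), nrow = 1, dimnames = list("s1", c("a", "b")))
  expect_equal(unname(detect_presence(m, 0)[1, ]), c(TRUE, TRUE))
  # 1/100 = 1% is not > 1%
  expect_equal(unname(detect_presence(m, 0.01)[1, ]), c(TRUE, FALSE))
  m2 <- matrix(c(94L, 6L), nrow = 1, dimnames = list("s1", c("a", "b")))
  expect_equal(unname(detect_presence(m2, 0.05)[1, ]), c(TRUE, TRUE))
  # failed samples are excluded
  m3 <- rbind(m, zero = c(0L, 0L))
  expect_equal(rownames(detect_presence(m3, 0)), "s1")
  expect_error(detect_presence(m, 1), "domain")
})

test_that("aggregation sums counts, ORs booleans, and 'all' is identity", {
  tax <- toy_taxonomy()
  cnt <- matrix(c(3L, 5L, 7L), nrow = 1,
                dimnames = list("s1", c("sp_pvulgaris", "sp_plunatus",
                                        "sp_rice")))
  g <- aggregate_taxa(cnt, tax, "genus")
  expect_equal(unname(g["s1", "g_phaseolus"]), 8)
  expect_equal(unname(g["s1", "g_oryza"]), 7)
  f <- aggregate_taxa(cnt, tax, "family")
  expect_equal(unname(f["s1", "f_fabaceae"]), 8)
  boolm <- cnt > 4
  gb <- aggregate_taxa(boolm, tax, "genus")
  expect_true(gb["s1", "g_phaseolus"])  # OR of {FALSE, TRUE}
  expect_identical(aggregate_taxa(cnt, tax, "all"), structure(
    cnt, n_taxa_in_comparison = 3L))
  # taxa with no ancestor at the level drop out of the comparison
  derep <- dereplicate_amplicons(data.frame(
    sequence = c("GGGGTTTTAAAA", "GGGGTTTTAAAA"),
    taxid = c("sp_malus", "sp_pyrus"), stringsAsFactors = FALSE))
  db <- curate_taxonomy(derep, tax)
  mg <- db$entries$taxid[1]
  cnt2 <- matrix(c(3L, 7L), nrow = 1,
                 dimnames = list("s1", c(mg, "sp_rice")))
  g2 <- aggregate_taxa(cnt2, db$taxonomy, "genus")
  expect_equal(attr(g2, "n_taxa_in_comparison"), 1L)
  f2 <- aggregate_taxa(cnt2, db$taxonomy, "family")
  expect_equal(sort(colnames(f2)), c("f_poaceae", "f_rosaceae"))
  expect_error(aggregate_taxa(cnt, tax, "order"), "domain")
})

test_that("pooled metrics match enumeration on a one-sample example", {
  taxa <- c("A", "B", "C", "D")
  det <- matrix(c(TRUE, TRUE, TRUE, FALSE), nrow = 1,
                dimnames = list("s1", taxa))
  diary <- matrix(c(TRUE, TRUE, FALSE, TRUE), nrow = 1,
                  dimnames = list("s1", taxa))
  rep <- concordance_metrics(det, diary)
  expect_equal(rep$tp, 2L)
  expect_equal(rep$fp, 1L)
  expect_equal(rep$fn, 1L)
  expect_equal(rep$recall, 2 / 3)
  expect_equal(rep$precision, 2 / 3)
  ident <- concordance_metrics(diary, diary)
  expect_equal(c(ident$recall, ident$precision, ident$fmeasure), c(1, 1, 1))
})

test_that("micro-averaged metrics equal the per-cell tally on random data", {
  set.seed(77)
  for (i in 1:10) {
    taxa <- paste0("t", 1:10)
    samples <- paste0("s", 1:20)
    det <- matrix(runif(200) < 0.3, 20, 10, dimnames = list(samples, taxa))
    diary <- matrix(runif(200) < 0.4, 20, 10, dimnames = list(samples, taxa))
    want <- oracle_tally(det, diary)
    got <- concordance_metrics(det, diary)
    expect_equal(got$tp, want$tp)
    expect_equal(got$fp, want$fp)
    expect_equal(got$fn, want$fn)
    expect_equal(got$recall, want$tp / (want$tp + want$fn))
    expect_equal(got$precision, want$tp / (want$tp + want$fp))
  }
})

test_that("per-taxon error rates follow the NA and all-detected conventions", {
  samples <- paste0("s", 1:10)
  det <- matrix(FALSE, 10, 3, dimnames = list(samples, c("A", "B", "C")))
  diary <- matrix(FALSE, 10, 3, dimnames = list(samples, c("A", "B", "C")))
  det[1:3, "A"] <- TRUE                  # A: never in diary, detected in 3/10
  det[, "B"] <- TRUE                     # B: detected everywhere
  diary[1:4, "B"] <- TRUE
  det[1:2, "C"] <- TRUE; diary[1:2, "C"] <- TRUE  # C: perfect agreement
  er <- taxon_error_rates(det, diary)
  a <- er[er$taxid == "A", ]
  expect_true(is.na(a$fnr))
  expect_equal(a$fpr, 0.3)
  b <- er[er$taxid == "B", ]
  expect_equal(b$fpr, 1)
  expect_equal(b$fnr, 0)
  c3 <- er[er$taxid == "C", ]
  expect_equal(c3$fpr, 0)
  expect_equal(c3$fnr, 0)
  # taxon in every diary and detected everywhere: no negatives at all
  det2 <- matrix(TRUE, 10, 1, dimnames = list(samples, "D"))
  diary2 <- matrix(TRUE, 10, 1, dimnames = list(samples, "D"))
  er2 <- taxon_error_rates(det2, diary2)
  expect_equal(er2$fpr, 1)
  expect_equal(er2$fnr, 0)
  expect_equal(attr(er, "n_high_fpr"), 1L)  # only B exceeds 0.5
})

test_that("venn partition reports whole-percent shares of the union", {
  both <- paste0("b", 1:38)
  dna <- paste0("d", 1:9)
  diary_only <- "coffee"
  v <- venn_partition(c(both, dna), c(both, diary_only))
  expect_equal(v$n_both, 38L)
  expect_equal(v$n_dna_only, 9L)
  expect_equal(v$n_diary_only, 1L)
  expect_equal(c(v$pct_both, v$pct_dna_only, v$pct_diary_only), c(79, 19, 2))
  same <- venn_partition(c("x", "y"), c("x", "y"))
  expect_equal(c(same$pct_both, same$pct_dna_only, same$pct_diary_only),
               c(100, 0, 0))
  disj <- venn_partition(c("a", "b"), c("c", "d"))
  expect_equal(c(disj$pct_both, disj$pct_dna_only, disj$pct_diary_only),
               c(0, 50, 50))
})

test_that("the metric grid enumerates all cells and recall shrinks with tau", {
  tax <- toy_taxonomy()
  set.seed(31)
  taxa <- c("sp_pvulgaris", "sp_plunatus", "sp_rice", "sp_malus")
  samples <- paste0("s", 1:12)
  cnt <- matrix(rpois(48, 40) * (runif(48) < 0.5), 12, 4,
                dimnames = list(samples, taxa))
  cnt[rowSums(cnt) == 0, 1] <- 5
  diary <- matrix(runif(48) < 0.4, 12, 4, dimnames = list(samples, taxa))
  subsets <- list(all = samples, firsthalf = samples[1:6])
  grid <- metric_grid(cnt, diary, tax, subsets = subsets,
                      levels = c("all", "genus", "family"),
                      thresholds = c(0, 0.01, 0.05))
  expect_equal(nrow(grid), 2 * 3 * 3)
  for (sub in names(subsets)) {
    for (lev in c("all", "genus", "family")) {
      rows <- grid[grid$subset == sub & grid$level == lev, ]
      rows <- rows[order(rows$threshold), ]
      expect_true(all(diff(rows$recall) <= 1e-12))
    }
  }
  # each grid cell is reproducible from the component operations
  cell <- grid[grid$subset == "all" & grid$level == "genus" &
                 grid$threshold == 0.01, ]
  det <- detect_presence(aggregate_taxa(cnt, tax, "genus"), 0.01)
  ref <- concordance_metrics(det, aggregate_taxa(diary, tax, "genus"))
  expect_equal(cell$recall, ref$recall)
  expect_equal(cell$precision, ref$precision)
})

test_that("alignment errors are raised for mismatched vocabularies", {
  det <- matrix(TRUE, 1, 2, dimnames = list("s1", c("A", "B")))
  diary <- matrix(TRUE, 1, 2, dimnames = list("s1", c("A", "C")))
  expect_error(concordance_metrics(det, diary), "alignment")
  diary2 <- matrix(TRUE, 1, 2, dimnames = list("s2", c("A", "B")))
  expect_error(concordance_metrics(det, diary2), "alignment")
})

test_that("aggregating an all-true presence matrix stays all-true", {
  tax <- toy_taxonomy()
  m <- matrix(TRUE, 3, 4, dimnames = list(
    paste0("s", 1:3), c("sp_pvulgaris", "sp_plunatus", "sp_rice", "sp_malus")))
  expect_true(all(aggregate_taxa(m, tax, "genus")))
  expect_true(all(aggregate_taxa(m, tax, "family")))
})
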