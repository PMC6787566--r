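# dietbarcode

Characterising the plant component of human diets by DNA metabarcoding of
stool, and benchmarking those DNA-based detections against written diet
records.

Self-reported diet data (food diaries, 24-h recalls, food-frequency
questionnaires) are limited by human memory and reporting behaviour. An
alternative is to sequence the food DNA that survives digestion: the P6 loop
of the chloroplast *trn*L (UAA) intron is a short, variable plant marker
flanked by conserved primer sites, widely used for herbivore diet analysis
and applicable to human stool. `dietbarcode` implements the full analysis
path for such a study, for researchers in nutrition, microbiome science, and
molecular ecology:

- **Reference-database curation** — in-silico PCR against annotated plant
  sequences (both strands, IUPAC-aware, ≤ 4 mismatches per primer site,
  amplicons of 9–300 bp), dereplication, and taxonomic curation that
  collapses genetically indistinguishable taxa (e.g. apple and pear, or
  rice/rye/wheat, which are identical at *trn*L-P6) into genus or
  multi-genus groups, with an audit trail of every reassignment.
- **Read processing** — MID-tag demultiplexing, primer location (≤ 2
  mismatches per site), removal of reads with mean Phred quality ≤ 32 over
  the P6 region, any ambiguous base, or length < 9 bp, a global floor of 10
  reads per unique sequence across the run, and taxonomic assignment by
  100% sequence identity only. Every input read is conserved across the
  accounting categories.
- **Diary coding** — a common-name lexicon maps diary entries onto the same
  curated taxon vocabulary (broccoli/cabbage → *Brassica oleracea*,
  "beans" → *Phaseolus*, …), with exclusions applied identically on both
  sides and each stool sample paired to the diary of the *previous* day.
- **Concordance metrics** — pooled recall `R = TP/(TP+FN)`, precision
  `P = TP/(TP+FP)`, and the F-measure `F = 2RP/(R+P)`, evaluated over a grid
  of sample subsets × taxonomic levels (all / species / genus / family,
  summing counts or OR-ing presence bits) × relative-abundance detection
  thresholds (> 0%, 1%, 5%); per-taxon FPR/FNR with explicit NA conventions;
  and the three-way taxon partition (both methods / DNA only / diary only).
- **Community statistics** — Bray-Curtis and Jaccard dissimilarity, Mantel
  tests and one-factor PERMANOVA with add-one permutation p-values
  (`p = (1 + #{stat* ≥ stat}) / (1 + N)`), and Bonferroni correction across
  period-wise tests that keep one sample per participant.
- **A synthetic feeding study** — a seeded generator reproducing the design
  of an 11-participant controlled-feeding experiment (baseline, plant arm,
  washout, baseline, animal arm, washout), with shared P6 haplotypes, a
  coffee-like non-amplifying taxon, diary omissions, hidden trace
  ingredients, amplification failures, and per-base sequencing errors — so
  the whole pipeline is testable against known ground truth.

## Worked example

Simulate a 4-participant study with one shared haplotype pair, one
non-amplifying taxon, 10% diary omission, and 30% amplification failure,
then run every stage:

```r
library(dietbarcode)
cfg <- study_config(n_participants = 4, n_plant_taxa = 20,
                    shared_sequence_groups = list(c(1, 2)),
                    non_amplifying_taxa = 3, reads_per_sample = 500,
                    diary_omission_prob = 0.1, amplification_failure_prob = 0.3,
                    seed = 20)
res <- run_study_pipeline(cfg)
res
#> Simulated feeding-study benchmark
#>   samples sequenced: 120 | taxa in db: 19
#>   all/all/>0%: recall=0.93 precision=0.82 F=0.87
```

The curated database holds 19 taxa, not 20: the shared pair collapsed into
one multi-genus group. The concordance grid shows the characteristic
behaviour of the benchmark — raising the detection threshold trades recall
for precision, and diary omissions surface as apparent false positives:

```r
subset(res$grid, level == "all")
#>        subset level threshold n_samples  tp fp  fn recall precision fmeasure
#> 1 all samples   all      0.00        73 387 85  30   0.93      0.82     0.87
#> 3 all samples   all      0.01        73 350 78  67   0.84      0.82     0.83
#> 5 all samples   all      0.05        73 229 53 188   0.55      0.81     0.66
```

Recall falls from 0.93 to 0.55 as the threshold rises from >0% to >5%,
while precision stays near 0.82 — the false positives here are real intake
that the simulated diarists failed to record. The taxon partition shows one
diary-only taxon: the coffee-like taxon whose DNA never amplifies
(`res$venn$n_diary_only` is 1, 5% of the union). Period-wise Mantel tests
(`res$mantel`) compare the Bray-Curtis structure of the DNA counts with the
Jaccard structure of the diary within each study window, Bonferroni-adjusted.

Individual operations are exported and composable: `insilico_pcr()`,
`build_reference_db()`, `process_reads()`, `code_diary()`,
`pair_to_samples()`, `metric_grid()`, `mantel_test()`, `permanova()`, and
the simulator (`simulate_reference()`, `simulate_feeding()`,
`simulate_reads()`, `make_fixtures()`).

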