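---
title: "Benchmarking dietary plant DNA metabarcoding against diet records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking dietary plant DNA metabarcoding against diet records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietbarcode)
```

## The problem

Human diet assessment usually relies on self-reporting, which is limited by
memory and reporting behaviour. DNA metabarcoding offers an orthogonal
readout: plant food DNA that survives digestion can be amplified from stool
at the *trn*L(UAA)-P6 chloroplast locus — a short marker with conserved
primer sites and enough interspecific variation to identify most food
plants to species or genus. `dietbarcode` implements the complete analysis
for such a study: curating a P6 reference database, turning raw reads into
a sample × taxon count table, coding written diet diaries onto the same
taxon vocabulary, and quantifying the agreement between the two detection
surfaces.

Because the two surfaces disagree for two very different reasons — the
sequencing may detect a food the diarist failed to record, or may produce a
spurious call — the benchmark deliberately prioritises comparisons against
foods *reported present*. Omission of foods from diaries (memory lapses,
hidden ingredients of processed foods) is taken to be far more likely than
the invention of foods never eaten, so a "false positive" of the DNA method
is often a true detection missing from the record. The synthetic-study
generator encodes exactly this asymmetry, which is what makes the
pipeline's behaviour testable.

## Reference-database curation

`insilico_pcr()` scans a template on both strands for the forward primer
site and the reverse-primer binding site, ungapped, with IUPAC degeneracy
honoured on the primer side only; an `N` in the template never matches.
The mismatch allowance (default 4 for database construction) is applied
*per primer*, not summed — this matches the semantics of ecoPCR-style
tools; it is exposed as a parameter for users who prefer a summed budget.
Every valid primer-site pairing is reported (a template may yield several
amplicons), the amplicon excludes the primers, its length must fall within
9–300 bp inclusive, and coordinates are reported 0-based half-open with the
strand recorded.

`dereplicate_amplicons()` merges byte-identical amplicons, pooling source
taxa and provenance. `curate_taxonomy()` then resolves each unique
sequence to a single taxon: species-unique sequences keep their species;
sequences shared by congeneric species lift to the genus (various
*Phaseolus* species become "beans" at genus rank); sequences shared across
genera of one family become a multi-genus group named by its member genera
("Malus/Pyrus" — apples and pears are genuinely identical at this locus, as
are rice, rye, and wheat within Poaceae); sequences shared across families,
or not identifiable to genus level or better, are dropped with a warning.
Cross-family collapse is not offered because no common food motivates it;
this is the one genuinely open curation choice and the conservative option
(dropping) was taken. Curation is idempotent, and an audit table records
every reassignment. `apply_exclusions()` removes taxa (e.g. cranberry,
spices whose reference identity is uncertain) and exports the same list for
the diary side, keeping both vocabularies comparable.

## Read processing

`process_reads()` chains four operations whose accounting conserves every
input read:

1. **Demultiplexing** by exact MID tag at the 5′ end (longest tag wins when
   lengths differ); unmatched reads are counted and discarded.
2. **Screening**: the primers are located with at most 2 mismatches each
   (ungapped, IUPAC-aware, via `Biostrings::vmatchPattern`); the P6 region
   between them is extracted and rejected if its mean Phred quality is
   ≤ 32, if it contains any non-ACGT base, or if it is shorter than 9 bp.
   The quality mean is computed over the extracted P6 region (after primer
   removal), since that is the sequence whose identity matters downstream;
   whether the original protocol averaged before or after trimming is not
   documented, and the post-trim choice is the stricter reading. The
   cutoff is non-strict: a mean of exactly 32 is rejected.
3. **Dereplication with a global floor**: identical P6 sequences are
   tallied across *all* samples of the run (including any blanks), and
   unique sequences seen fewer than 10 times in total are dropped — once,
   before assignment, matching the stated order of operations.
4. **Exact-match assignment**: only sequences with 100% identity to a
   database entry are retained; a curated taxon may be fed by several
   haplotypes, whose counts are summed. Near-matches go to an unassigned
   report. No clustering, denoising, or LCA fallback is provided — the
   method is defined by perfect matches.

Samples with zero assigned reads are flagged as failed and excluded from
all concordance denominators, mirroring the analysis of PCR-positive
samples only.

## Diary coding and pairing

`code_diary()` maps free-text food names through an editable lexicon onto
curated taxa; names mapping to one taxon combine by OR, excluded names
contribute nothing, and unknown names land in an `uncoded` report rather
than silently disappearing or aborting the run (mirroring the manual
curation step such studies require). Quantities are ignored: diaries enter
the analysis as presence/absence only. `pair_to_samples()` implements the
day-prior rule — a stool sample collected on day *d* reflects the diary of
day *d* − 1 — and drops samples lacking a day-prior diary. Gut retention
time actually varies around that one-day lag; modelling that variability is
out of scope, and the fixed lag is applied consistently on both the truth
and analysis sides of the simulation. Composite dishes are attributed to
the single day they were recorded.

## Concordance metrics

All headline metrics are *micro-averaged*: TP, FP, and FN are pooled over
every (sample, taxon) cell of the subset before forming recall, precision,
and the F-measure (harmonic mean, 0 when both are 0). Dataset-level
reporting of single values is the convention being reproduced; per-sample
macro-averaging can be composed from the exported operations if wanted.
Detection at threshold τ requires a taxon's count to *strictly* exceed τ
times the sample total (τ = 0 therefore means any nonzero count).
Aggregation to genus or family sums counts and ORs presence bits; taxa
with no ancestor at the requested level leave the comparison, and the
number that remain is reported alongside each grid row — which is why both
recall and precision can rise with coarser levels even though they are
inversely related at fixed taxa. Per-taxon error rates follow two explicit
conventions: FNR is NA for taxa never recorded in any diary (denominator
zero), and a taxon detected in every sample with no negatives of either
kind reports FPR = 1 and FNR = 0. Report rendering rounds half away from
zero to two decimals; internal values keep full precision.

## Community statistics

Bray-Curtis (abundance-weighted, on per-sample relative abundances) serves
the DNA side; Jaccard serves the presence/absence diary side. Mantel tests
use Pearson correlation of upper-triangle distances, one-tailed for
positive association, with the add-one permutation convention
p = (1 + #{r\* ≥ r})/(1 + N); PERMANOVA partitions squared distances into
between- and within-group sums of squares (the decomposition closes to
1 × 10⁻⁹ by construction and is asserted in tests). Defaults are 999
permutations — standard ecological practice, and consistent with the
granularity of permutation p-values such studies report — with a required
seed for reproducibility; both tests also accept an explicit permutation
matrix, in which case the p-value is the exact enumeration fraction.
Period-wise testing keeps one sample per participant per study window to
avoid pseudo-replication; the *latest* sample in the window is retained
(the selection rule is not documented in the source protocol; latest was
chosen as the sample most shaped by that window's diet) and Bonferroni
correction is applied across windows. Windows with fewer than three usable
participants are skipped with a warning.

## The synthetic study generator

`study_config()` defaults encode the emulated design: 11 participants;
periods of 4 (baseline), 5 (plant arm), 6 (washout), 4 (baseline), 5
(animal arm), and 6 (washout) days; 45 plant taxa; one apple/pear-like
shared-haplotype pair plus one rice/rye/wheat-like trio; one coffee-like
taxon whose DNA never amplifies; and a 50% per-sample amplification
failure rate (half of real stool samples in such studies yield no PCR
band). Parameters the emulated study does not pin down were fixed once at
values a practitioner would call realistic and are exposed as free
parameters: 10% diary omission, 5% trace-ingredient probability (the true
frequency of hidden ingredients in free-living diets is unknown), mean
depth 2,000 reads/sample, log-normal abundance skew σ = 1.5, per-base
substitution error 0.002, mean Phred 36.

Mechanics worth knowing when interpreting test results:

- Intake on day *d* is written to the stool sample of day *d* + 1, so the
  day-prior pairing is exact by construction.
- Free-eating days draw each taxon independently (≈ 8 taxa/day); plant-arm
  days draw from a fixed 12-item menu; animal-arm days draw from a
  near-empty residual set, so zero-plant days occur.
- Relative abundances are renormalised log-normal draws; read counts per
  taxon are multinomial at a Poisson depth.
- Reads are MID + forward primer + P6 + reverse-complemented reverse
  primer. Substitution errors (no indels — exact-match assignment semantics
  stay testable; indel robustness is a non-goal) apply downstream of the
  MID, so demultiplexing is exact; qualities are integers near the mean,
  Phred+33.
- Diaries never invent foods: the diary matrix is the true intake with
  trace ingredients removed and independent omissions applied. Apparent
  precision against such diaries converges to 1 − ω under otherwise ideal
  conditions, which the test suite verifies at ω = 0.2 within ±0.05.

What passing tests therefore show — and what they do not: the pipeline
provably recovers a noiseless study perfectly (recall = precision = F = 1)
and degrades in the quantitatively expected ways under omission, error,
and thresholding. The generator does not emulate PCR amplification bias
between taxa, chimeras, DNA degradation by cooking, variable gut retention,
or correlated day-to-day menus, so real-data performance claims cannot be
read off these simulations; the microbiome/SCFA comparisons use generic
random matrices only.

## Numerical choices and problem sizes

Ties in permutation tests are counted in favour of the null (≥ with a
1 × 10⁻¹² tolerance so the identity permutation is never missed). The
screening order of rejection reasons is primer → quality → ambiguity →
length (a zero-length extraction reports `length`). Test problem sizes were
chosen as the smallest that make each property sharp: the in-silico PCR
oracle runs on 200+ random templates up to 5 kb; exhaustive permutation
equivalence uses n = 5 and 6; null-uniformity uses 40–60 replicate
datasets at 199–999 permutations; the end-to-end fixtures use 3–11
participants at 150–2,000 reads/sample.

## Known limitations

Exact-match assignment means a single sequencing error in the P6 region
unassigns a read (by design); abundance is not calibrated to intake mass;
the lexicon ships with common combined-taxon conventions but any real study
must extend it; and the curation rule drops cross-family shared sequences
rather than lifting them, which would misbehave for markers far less
resolving than trnL-P6.
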