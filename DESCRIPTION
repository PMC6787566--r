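Package: dietbarcode
Title: Dietary Plant DNA Metabarcoding of Stool Benchmarked Against Diet Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Characterises the plant component of human diets from trnL(UAA)-P6
    chloroplast amplicon sequencing of stool, and benchmarks the DNA-based
    detections against written diet records. Provides in-silico PCR curation of
    a P6 reference database (mismatch-tolerant primer search, dereplication,
    collapsing of genetically indistinguishable taxa), a read-processing
    pipeline (demultiplexing, primer trimming, quality and length filtering,
    global count floor, exact-match taxonomic assignment), diet-diary coding
    with a common-name lexicon and day-prior pairing, concordance metrics
    (recall, precision, F-measure, per-taxon error rates, taxonomic
    aggregation, relative-abundance detection thresholds), permutation-based
    community statistics (Bray-Curtis, Jaccard, Mantel, PERMANOVA), and a
    synthetic controlled-feeding study generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
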