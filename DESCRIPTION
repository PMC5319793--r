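Package: editevol
Title: Evolutionary Analysis of A-to-I RNA Editing Across Species
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of adenosine-to-inosine (A-to-I) RNA editing
    across a species phylogeny. Identifies and quantifies editing sites from
    per-site pileup counts, estimates false-positive rates against an
    ADAR-null sample, models cis-regulation of editing through the ADAR
    triplet motif and predicted double-stranded RNA stems (editing
    complementary sequences), dates editing events on a species tree by
    parsimony, classifies sites by evolutionary constraint from per-base
    conservation tracks, fits random-forest models of editing change, and
    tests 3'UTR editing for expression effects and miRNA seed-match
    gains/losses. Ships a fully specified synthetic-data generator that
    emulates the statistical structure every stage assumes, so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    ape,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
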