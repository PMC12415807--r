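Package: ednabench
Title: Benchmarking Toolkit for Marker-Gene eDNA Taxonomic Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based benchmarking of taxonomic classifiers for
    environmental DNA (eDNA) metabarcoding with mitochondrial markers
    (12S, 16S, COI). Curates marker reference databases (mislabel
    detection by self-alignment and lowest-common-ancestor conflicts),
    builds clade-exclusion database variants, performs native in-silico
    PCR and paired-end read simulation, derives amplicon sequence
    variants (ASVs) with ground-truth provenance, generates random and
    surrogate negative controls, runs two built-in classifiers (top-hit
    with LCA reduction; a hashed k-mer naive Bayes classifier with
    bootstrap confidence), adapts external classifier output for
    scoring, and evaluates predictions with species-level confusion
    counts, accuracy, precision, recall, F1 and F0.5.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
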