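Package: evocor
Title: Functional Linkage Prediction from Phylogenetic Profiles and
    Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts functionally related genes by combining binary
    phyletic (phylogenetic) profiles with tissue-wide co-expression.
    Builds presence/absence vectors over a fixed species universe from
    profile-HMM homology hits (HMMER3 per-domain tabular output), scores
    co-evolution by pairwise Hamming distance, refines candidate lists by
    Pearson expression correlation under a two-key deterministic ranking,
    and evaluates result lists by split-half annotation-term overlap with
    Kolmogorov-Smirnov and Wilcoxon rank-sum comparisons.  Includes a
    synthetic-data generator with planted co-evolving, co-expressed gene
    modules so the whole pipeline is testable offline, and a command-line
    interface wiring the stages together.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
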