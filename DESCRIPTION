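Package: srbns
Title: Structured RNA Bind-n-Seq Analysis of Stem-Loop Binding Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structured RNA Bind-n-Seq (sRBNS) experiments, in which
    a randomized loop is presented on constant stem-loop scaffolds and
    protein-bound libraries are sequenced against the input pool. Provides
    pool design and loop-variant enumeration, constant-arm read assignment
    and counting from FASTQ, per-variant enrichment (E-value) and z-score
    significance analysis with enrichment-weighted sequence logos, an
    equilibrium-binding read simulator for end-to-end validation, a
    constrained hairpin partition-function folder with an exhaustive
    ensemble oracle, and a 3'-UTR scanner that predicts CDE/ADE-like
    stem-loop elements from degenerate loop motifs, stem length and
    hairpin folding probability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
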