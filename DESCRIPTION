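Package: alushare
Title: Split-Read Detection and Cross-Genus Sharing Analysis of Alu
    Insertion Polymorphisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a split-read
    pipeline for mobile element insertion (MEI) calling and downstream
    population statistics. Simulates paired-end whole-genome sequencing
    cohorts with planted Alu retrotransposon insertions under configurable
    sharing structures, detects insertion junctions by cleaving the
    Alu-matching segment of candidate split reads and uniquely mapping the
    residual flank, genotypes loci across individuals into a
    presence/absence matrix, and reproduces the associated statistics:
    per-bin sharing counts with one-way ANOVA and Bonferroni post-hoc
    t-tests, species-indicative insertion sets with normal z-scores,
    PCR-style validation accounting, a 5'-flank-length read filter with
    before/after comparison, and Alu subfamily assignment by percent
    divergence to a consensus library.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    graphics,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
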