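Package: imprintatlas
Title: Calling Canonical and Non-Canonical Genomic Imprints from Reciprocal
    F1 Hybrid Allele-Specific Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying imprinted genes and parent-of-origin
    differentially methylated regions (DMRs) from allele-resolved expression
    and methylation data generated in reciprocal F1 hybrid crosses.
    Implements paternal-expression-ratio filtering with sentinel codes,
    per-transcript t-tests with Bonferroni control, a linear-model path with
    empirical-Bayes variance moderation and a fold-change gate, a smoothing
    DMR caller with gamete-integrated origin classification, an integrator
    that labels genes as canonical or non-canonical imprints (including
    ZFP57 motif scanning and oocyte H3K27me3 overlap), cross-species
    comparison of oocyte epigenomes over syntenic 1-kb bins, and imprinted
    X-chromosome-inactivation skew tests. A synthetic-data generator
    produces reciprocal-cross datasets with known truth so every stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
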