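Package: apashift
Title: Alternative Polyadenylation Shift Analysis from 3'-End Sequencing
Version: 0.1.0
Authors@R:
    person("APA", "Maintainer", email = "maintainer@apashift.org", role = c("aut", "cre"))
Description: Quantifies alternative polyadenylation (APA) from 3'-end
    sequencing (PAC-seq style) read evidence: merges per-read cleavage
    positions into poly(A)-site features, maps them to an annotated
    poly(A)-site database, applies count-support filters, tests per-gene
    differential site usage with a Dirichlet-multinomial likelihood-ratio
    test, and summarises the direction of change with a weighted mRNA
    length score. Companion arms profile UGUA (CFIm25-binding) motif
    frequency around shifted cleavage sites, integrate label-free
    proteomics via downshifted-Gaussian imputation and an empirical-Bayes
    moderated t-test with a conditional chi-square battery, and provide a
    simplified negative-binomial differential-expression test on
    site-aggregated gene counts. A synthetic-data generator emulating a
    two-condition 3'-end sequencing study with a matched proteome makes
    every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    Rsamtools,
    GenomicAlignments,
    jsonlite
Config/testthat/edition: 3
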