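Package: methaplo
Title: Methylation Haplotype Blocks, MHL Scoring and Epi-Cluster Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for subtype discovery from read-level CpG methylation
    haplotypes: identification of methylation haplotype blocks (runs of
    tightly coupled CpG sites, adjacent-pair linkage r-squared), block-level
    methylation haplotype load (MHL) scoring, rank-2 non-negative matrix
    factorization epi-clustering with Methy-High/Methy-Low labelling,
    projection of block classifiers onto array beta-value matrices,
    differential-block calling with genome-annotation enrichment, and
    survival association (Kaplan-Meier, log-rank, Cox). Includes a synthetic
    cohort generator emulating two latent methylation subtypes so every
    stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    survival,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
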