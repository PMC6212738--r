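Package: wssGWAS
Title: Weighted Single-Step Genome-Wide Association for Sow Reproduction Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for weighted single-step genomic BLUP
    association analysis (wssGWAS) of multi-trait sow reproduction data:
    pedigree numerator relationship matrices and their inverses, genomic
    relationship matrices with iterative SNP variance weighting, combined
    H-inverse assembly, Henderson mixed-model equations, EM-REML variance
    components, GEBV-to-SNP-effect back-solving, sliding-window
    percent-of-genetic-variance scans, and candidate-region annotation
    against local gene intervals. Includes a gene-dropping simulator with
    known ground truth (planted QTL, variance components) so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
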