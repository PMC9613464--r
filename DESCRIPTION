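Package: lsctools
Title: Quantitative Analysis of Leukemia Stem Cell Hierarchies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing leukemia stem cell (LSC) driven AML
    hierarchies from functional and genomic assays: single-hit Poisson
    limiting-dilution analysis of xenograft engraftment with Wald or
    likelihood-ratio confidence bounds; detection of subclonal copy-number
    amplifications by projecting reference segments onto 1-kb binned
    copy-number tracks and rank-testing adjacent segments; discovery of
    clusters of cis-regulatory elements (COREs) from ATAC-seq peak sets with
    a predictability-coefficient ranking that separates LSC-containing from
    LSC-depleted fractions; and single-sample stemness signature scoring
    (Spearman correlation to a reference profile, weighted signature sums,
    and a rank-based running-sum enrichment score). A synthetic-data module
    generates every input the pipeline consumes so all stages are testable
    without access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
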