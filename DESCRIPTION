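Package: fsgsomics
Title: Multi-Omics Candidate Gene Prioritization for Recurrent FSGS Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An integrative genomic, transcriptomic and metabolomic pipeline
    for prioritizing candidate genes in small case-control transplant cohorts,
    modelled on the recurrent focal segmental glomerulosclerosis (rFSGS)
    study design. Implements two-stage group-presence filtering of annotated
    exonic variants, differential expression with three-cohort set algebra,
    hypergeometric gene-set over-representation with Benjamini-Hochberg
    correction, Jaccard/overlap-coefficient pathway crosstalk networks,
    evidence triangulation into a ranked candidate report, and an LC-MS
    metabolomics cascade (prevalence filtering, k-nearest-neighbour
    imputation, QC-based drift correction, PLS-DA with VIP selection, and
    metabolite ratio comparison). A deterministic synthetic cohort generator
    with a planted causal gene makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
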