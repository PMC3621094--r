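Package: proviscan
Title: Mining and Characterization of Full-Length Endogenous Betaretroviruses
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers full-length endogenous betaretroviruses (betaERVs) in
    genome scaffolds and transcriptome contigs. Implements a six-frame
    translated Smith-Waterman protein search with Karlin-Altschul E-values,
    three-gene (gag/pol/env) locus intersection, provirus delineation by
    LTR-pair self-alignment with target-site-duplication and polypurine-tract
    detection, annotation of ORFs, tRNA primer-binding sites, enzymatic and
    structural motifs and gene intactness, molecular-clock dating of
    integrations from LTR divergence via T = (D/R)/2, and rule-based
    assignment to eight betaretroviral sub-groups. Ships a seeded synthetic
    genome generator that plants decayed proviruses with full ground truth so
    the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
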