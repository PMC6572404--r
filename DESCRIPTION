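Package: methscan
Title: Whole-Genome Bisulfite Sequencing Methylome Analysis with
    Sliding-Window DMR Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing plant whole-genome bisulfite sequencing
    (WGBS) methylomes starting from per-cytosine count reports: strand-aware
    CG/CHG/CHH context classification, exact-binomial methylated-site calling
    against the bisulfite conversion-failure rate, weighted methylation
    levels at site, window and genomic-feature resolution, 9-mer sequence
    preference tables around methylated cytosines, metagene profiles
    stratified by expression class, sliding-window Fisher-exact calling of
    differentially methylated regions (DMRs) with merging and gene
    association, DMR-by-DEG enrichment, and clone (Sanger) bisulfite percent
    methylation. A fully deterministic simulator plants methylation
    structure, DMRs and expression associations into synthetic genomes so
    every stage can be benchmarked against known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Rcpp,
    jsonlite,
    yaml,
    Biostrings,
    rtracklayer,
    BiocGenerics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
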