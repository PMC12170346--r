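Package: clonotrack
Title: Longitudinal Paired Single-Cell TCR Repertoire Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for paired single-cell T cell receptor (TCR) repertoire
    analysis across timepoints: quality control of paired alpha/beta chain
    tables (AIRR Rearrangement or 10x contig format), clonotype definition
    by CDR3 alignment distance (BLOSUM62, affine gaps), clonal expansion
    and repertoire diversity statistics (size spectra, Shannon entropy,
    D50), longitudinal clonotype tracking with phenotype-transition tables,
    exact r-by-c Fisher tests and empirical transition matrices,
    GLIPH-style CDR3 motif clustering (global exchangeable-substitution
    edges plus enriched local k-mer motifs), differential expression and
    gene-set enrichment between expanded and non-expanded clones, and a
    synthetic longitudinal cohort generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
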