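Package: mtmosaic
Title: Mitochondrial DNA Mosaicism: Heteroplasmy Calling, Drift Simulation
    and Turnover/Mutation-Rate Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing mitochondrial DNA (mtDNA) mosaicism in
    single-cell-derived clones: quality filtering of candidate heteroplasmic
    calls, a locus-specific background-noise panel with relative-gap
    thresholding, classification of variants into fertilized-egg heteroplasmy
    and postzygotic mutations, drift summary statistics (clone-averaged VAF,
    fixation index, S_VAF, strand-asymmetric spectra), forward simulation of
    mtDNA turnover under mitotic (Polya-urn doubling plus random halving) and
    homeostatic (Moran replacement) models, MSE-rejection inference of
    turnover and per-base-pair mutation rates, dN/dS against a simulated
    neutral null, and a truth-labelled synthetic cohort generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    jsonlite,
    vcfR,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
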