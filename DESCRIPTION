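Package: taxomasst
Title: Taxonomically Informed MS/MS Spectral Library Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Search tandem mass spectrometry (MS/MS) spectra against a
    reference library of spectra acquired from microbial monocultures and
    aggregate the matches onto an NCBI-style taxonomic tree. Implements
    modified cosine scoring with optional precursor-mass-shift (analog)
    peak pairing, a precursor m/z index for fast candidate retrieval,
    exact and analog search with configurable thresholds, upstream match
    propagation with per-taxon match proportions, blank/QC/cell-line
    handling, tabular and interactive tree reports, a differential
    pipeline for extracting condition-unique microbial spectra from
    feature tables, and a deterministic synthetic-repository generator
    with planted ground truth for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
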