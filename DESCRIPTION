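Package: halokin
Title: Labeling Kinetics, Affinity and Enrichment Analysis for Split-Tag
    Complementation Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits second-order fluorescence-polarization labeling kinetics of
    peptide/protein split-tag complementation assays, aggregates
    per-concentration rates into EC50 estimates with Monte Carlo confidence
    intervals, determines equilibrium (saturation titration) and kinetic
    (bio-layer interferometry, global 1:1 model) binding affinities, and
    provides supporting assay computations: dye-corrected protein
    concentrations, Lambert-Beer substrate quantification, fluorescence
    turn-on fold changes, nanoDSF melting temperatures and Gaussian
    full-width-at-half-maximum of microscopy line profiles. Amino-acid
    enrichment of NNK saturation-mutagenesis libraries is computed from reads
    by position-based codon extraction. A synthetic-data generator emulates
    every assay so the whole pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
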