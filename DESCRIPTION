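Package: betapair
Title: Prediction of Hydrogen-Bonded Residue Pairings in Beta Strands
    from Predicted Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts which residue pairs form backbone hydrogen bonds
    between beta strands, starting from predicted residue-residue contact
    maps.  Paired strands leave contiguous diagonal (parallel) or
    anti-diagonal (antiparallel) ridges on a contact map; the package
    extracts gamma-normalized scale-space ridge height and orientation
    features, broadcasts sequence-level information (secondary-structure
    probabilities, amino-acid identity, alignment depth, chain length)
    onto the pair grid, and scores every residue pair with a residual
    convolutional network that combines row/column normalization with
    instance normalization.  A synthetic beta-sheet simulator with planted
    strand topologies makes training, cross-validated cutoff selection,
    precision/recall evaluation, and export of folding distance
    constraints fully reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
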