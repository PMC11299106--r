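Package: plasmidMOB
Title: MOB Typing of Plasmid Metagenomic Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mobilization (MOB) typing of plasmid sequences from metagenomic
    assemblies. Complete plasmid genomes are labeled by relaxase homology via
    a coverage/bitscore confidence score; DNA fragments are featurized as the
    mean of skip-gram k-mer word vectors and classified into ten MOB classes
    plus a nonmobilizable category by an ensemble of length-specific random
    forests, with length-weighted aggregation for metagenomic bins. Includes
    a synthetic plasmid benchmark generator and the associated evaluation
    suite (accuracy, Cohen's kappa, per-class balanced accuracy, harmonic
    mean, F1, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    ranger
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
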