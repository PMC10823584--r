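Package: icoreRF
Title: ICORE-Based Random Forest Prediction of Cancer Neo-Epitope Immunogenicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the immunogenicity of cancer neo-epitopes from
    mutant/wild-type peptide pairs and their HLA class I restriction.
    The pipeline extracts the ICORE (the 8-12-mer sub-peptide with the
    best predicted MHC presentation rank), derives positional weights
    from Kullback-Leibler information content of per-allele binding
    motifs, assembles amino-acid composition and mutation-aware features
    (rank-based agretopicity, BLOSUM62 and codon mutation scores, kernel
    self-similarity, physico-chemical descriptors, antigen expression),
    builds leakage-free cross-validation folds with a Hobohm-1
    redundancy scan over a BLOSUM62 k-mer peptide kernel, and trains a
    nested cross-validated ensemble of random forests whose scores are
    calibrated to percentile ranks against a mutated-proteome
    background. Includes a deterministic surrogate MHC rank predictor
    and a synthetic-data generator so the full pipeline runs and is
    testable without external binaries or restricted datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ranger,
    jsonlite,
    yaml,
    seqinr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    Biostrings,
    optparse
Config/testthat/edition: 3
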