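Package: coevoscore
Title: Coevolution-Based Variant Impact Scores from Protein Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the functional impact of protein missense variants from
    evolutionary coupling analysis of a multiple sequence alignment. Computes
    McLachlan-based substitution-correlation (McBASC) covariation between
    alignment columns, selects the top 2L couplings for a protein of length L,
    and scores each variant by the coevolution (CE) score: the product of the
    percentile-normalized coupling number (CN) of the mutated residue and the
    cost of coupling (CC), an entropy change of amino-acid pair distributions
    at coupled sites. Includes alignment and variant parsing with the standard
    column and homolog filters, a single-column conservation (CS) analog,
    classifier evaluation (ROC/AUC, accuracy-maximizing thresholds,
    union-rule score integration, Monte-Carlo cross-validation), and a
    synthetic coevolving-alignment generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
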