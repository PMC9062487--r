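Package: secretomeQC
Title: Quality Control and Characterization of Cell-Line Secretome Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational quality control and characterization for secretome
    and proteome experiments on cultured cells grown on xenogeneic matrices.
    Implements in-silico tryptic digestion with cross-species peptide
    ambiguity estimation, peptide-to-membrane-topology mapping with
    extracellular/intracellular purity statistics, marker-set contamination
    signal fractions, lysate-versus-secretome leakage screening via Spearman
    correlation of cytoplasmic proteins, intensity normalization (quantile and
    scaling-factor), sequential conditional-mean imputation, blocked
    differential expression with Benjamini-Hochberg correction, secretion-mode
    classification (signal peptide, extracellular vesicle, sheddome, hormones
    and granins), recapitulation scoring against reference expression
    profiles, and a seeded synthetic-data generator with planted ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    limma,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
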