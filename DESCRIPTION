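Package: phosfx
Title: Effector Classification from SILAC Phosphoproteomics with Kinase Motif Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns triple kinase-inhibitor (BRAF/MEK/ERK) SILAC phosphoproteomics
    into classified kinase effectors. Provides class I phosphosite filtering,
    heavy/light ratio computation with proteome normalization, an empirical-Bayes
    moderated one-sample t-test with Benjamini-Hochberg FDR control,
    control-calibrated modulation thresholds, intersection-based classification of
    shared versus inhibitor-specific effectors, and kinase specificity matrices
    (PSSMs) built from positional-scanning peptide-array quantifications with
    additive log-odds scoring of phosphosite flanking sequences. A synthetic-data
    module generates channel-level SILAC experiments and peptide-array counts with
    known ground truth so every stage of the pipeline can be validated by
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
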