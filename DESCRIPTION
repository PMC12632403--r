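Package: ubifunc
Title: Confidence Tiering, Conservation, Hotspots and Functional Scoring of Ubiquitination Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for large-scale ubiquitination-site (ubi-site)
    proteomics. Collapses PSM-level localization evidence to site
    probabilities, estimates false localization rates with decoy alanine
    residues and assigns cross-dataset Gold/Silver/Bronze confidence tiers;
    maps sites onto orthologue alignments and scores rule-based evolutionary
    conservation levels; detects ubiquitination hotspots in protein-domain
    alignments with a lysine-constrained permutation test; aggregates
    perturbation fold-changes, clusters conditions, flags regulated sites and
    runs competitive set tests; and trains an ensemble of class-weighted
    logistic regression models under protein-grouped cross-validation to
    produce a per-site functional score. Ships a synthetic-data module that
    generates inputs with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
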