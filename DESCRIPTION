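Package: crisprimerf
Title: Mixed-Effect Random Forest Modelling of Bacterial CRISPRi Depletion Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Predicts bacterial CRISPRi guide efficiency from pooled depletion
    screens. Depletion of a guide mixes the fitness cost of silencing the
    target gene with the efficiency of silencing itself; the package
    separates the two with a mixed-effect random forest fitted by
    expectation-maximization, in which a random forest over guide-sequence
    features captures guide efficiency (fixed effects) and per-gene linear
    random effects absorb gene- and dataset-level confounders. Includes guide
    enumeration and feature engineering (one-hot target context,
    hybridization energies, distances, operon context), cross-screen logFC
    fusion, read-count processing with non-targeting-guide TMM
    normalization, gene-wise cross-validation with screen-derived metrics,
    TreeSHAP-style feature attribution, and a synthetic screen simulator
    with a known gene/guide effect decomposition for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    Biostrings,
    edgeR,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
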