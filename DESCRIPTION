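Package: lectinspec
Title: Lectin-Glycan Specificity Analysis from Glycan Arrays, Calorimetry
    and Sequence Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for characterizing the carbohydrate-binding behavior of
    plant lectins. Parses condensed-IUPAC (CFG dialect) glycan structure
    strings into rooted trees, matches subtree motifs such as the N-glycan
    trimannosyl core pentasaccharide, and classifies N-glycans into
    high-mannose, complex and core-fucosylated categories. Reproduces
    glycan-microarray ranking statistics (replicate trimming,
    percent-of-maximum normalization per lectin concentration, average rank,
    z-score binder partitions), fits the one-site isothermal titration
    calorimetry binding model with full thermodynamic derivation
    (dG = dH - T dS = -RT ln Ka), scans lectin sequences for the
    mannose-binding carbohydrate-recognition-site consensus [QXDXNXVXY] and
    its extended hydrophobic form, and builds Neighbor-Joining phylogenies
    from number-of-differences distances with complete deletion. Seeded
    synthetic-data generators with ground truth support end-to-end recovery
    tests of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
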