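Package: cysredox
Title: Differential Cysteine Redox Proteomics from SILAC Biotin-Switch Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies per-cysteine redox states (reduced S-H, S-nitrosylated
    S-NO, reversibly oxidized S-OX) from SILAC peptide-evidence tables produced
    by biotin-switch labeling experiments. Peptides are classified by their
    cysteine chemistry labels, cysteines are localized to protein sites,
    site-level heavy/light ratios are normalized to protein-level ratios
    estimated from cysteine-free peptides, and biofilm versus planktonic
    conditions are compared with Student's tests, Benjamini-Hochberg FDR
    correction, fold-change thresholds and presence/absence ("only") rules.
    Includes an exact Wald-Wolfowitz runs test, a synthetic evidence generator
    with planted ground truth for validation, and tabular/volcano reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
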