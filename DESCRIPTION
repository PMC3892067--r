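Package: tipigtow
Title: Lower Protein-Limit Estimation from Tug-of-War Plasmid Copy Numbers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for genetic tug-of-war (gTOW) experiments that
    probe the lower expression limit of a protein via TEV-protease-induced
    degradation (TIPI-gTOW). Converts qPCR crossing points into per-cell
    plasmid copy numbers, computes the TEV/vector copy-number ratio and the
    relative copy-number-change statistic across gene-deletion panels with
    sign classification of genetic interactions, simulates deterministic
    ODE cell-cycle models with division events and a viability rule, scans
    a degradation-rate parameter for its largest viable value (the
    in-silico analogue of the tug-of-war), compares experimental and
    simulated interaction signs, and generates synthetic qPCR data with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
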