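Package: vitisvc
Title: Grapevine Xylem Embolism Vulnerability Curves and Regional Drought Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for grapevine xylem embolism vulnerability:
    computes percentage loss of hydraulic conductivity (PLC) from
    flow-centrifuge conductivity sweeps, fits the Pammenter sigmoid model
    (Psi50, slope) per plant with derived Psi12/Psi88 thresholds, detects
    embolism events in optical-vulnerability leaf image stacks and maps them
    onto stem water potential, computes xylem anatomical traits and
    theoretical Hagen-Poiseuille conductivity from vessel lumen tables,
    clusters varieties into four vulnerability classes by Ward hierarchical
    clustering of z-scored thresholds, and aggregates cluster weights over
    regional winegrape bearing-area tables into a drought-vulnerability risk
    index. Includes synthetic-data generators that emulate every input with
    known ground truth, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    minpack.lm,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
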