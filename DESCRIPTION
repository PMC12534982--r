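Package: fluxkin
Title: Expression-Constrained Metabolic Flux Analysis and DHODH Inhibition Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transcriptomics-constrained genome-scale metabolic
    modeling and enzyme-inhibition analysis around pyrimidine de novo
    synthesis. Provides a constraint-based metabolic model container with
    COBRA-style JSON and SBML-FBC input, dead-end pruning and sink-reaction
    curation, GPR-based integration of expression data into flux bounds,
    flux balance and flux variability analysis, treated-versus-control
    differential flux tables, MOMA gene-knockout prediction with a
    simplified robust metabolic-transformation score, dose-response (IC50)
    fitting with Cheng-Prusoff Ki and inhibition-mode classification, and
    nanoDSF melt-curve Tm extraction. Ships generators for a toy
    pyrimidine-metabolism network and simulated expression, inhibition-assay
    and melt-curve data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    quadprog,
    signal,
    stats,
    utils,
    xml2
Suggests:
    callr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
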