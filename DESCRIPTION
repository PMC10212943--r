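Package: optosec
Title: Secretion Burnout Analysis and Optogenetic Induction Control for Yeast Protein Production
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and optimizing heterologous protein secretion
    in continuously cultured yeast under optogenetic induction. Implements a
    three-state linear ODE model of production, trafficking and secretion with a
    staged calibration (reporter-strain fit of production and dilution rates,
    unit-scale calibration on a secreted reporter, per-induction CMA-ES fits of
    trafficking, secretion and degradation rates); an event-level flow-cytometry
    processing chain (channel correction, forward-scatter gating, strain
    demultiplexing by a constitutive blue marker, size and relative-promoter-unit
    normalization, pre-induction baseline subtraction); single-cell statistics
    that detect transient "secretion burnout" accumulator subpopulations
    (mean-plus-three-sigma classifier, Gaussian-mixture subpopulation split,
    induction and stress thresholds at five-percentage-point accumulator
    appearance); growth-rate inference from co-culture strain fractions; a
    duty-cycle feedback control law that holds the population mean stress at a
    target level; and a seeded agent-based simulator of the turbidostat,
    cytometer and immunobead secretion assay used to exercise the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
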