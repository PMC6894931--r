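Package: multipatch
Title: Virtual Rig, Synthetic Data and Analysis for Multineuron Patch-Clamp
    Connectivity Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for planning, simulating and analysing multineuron
    whole-cell patch-clamp (multipatch) experiments that map synaptic
    connectivity in brain slices. Provides session-plan combinatorics for
    clean-to-complete and clean-to-extend pipette-cleaning strategies, a
    virtual pneumatic pressure rig with a timed cleaning schedule, rigid
    (Kabsch) registration between manipulator and microscope coordinate
    frames with pipette target planning, a seeded generator of synthetic
    current- and voltage-clamp recordings with known ground-truth
    connectivity, extraction of passive and action-potential features with
    quality-control filters, template-scaling (Clements-Bekkers) detection
    of spontaneous EPSPs, evoked-connection calling on sweep-averaged
    traces, and connectivity statistics (Fisher's exact test, Wald
    confidence intervals for proportion differences, and TOST equivalence
    reports).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    signal,
    igraph
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'trace-methods.R'
    'multipatch-package.R'
    'RcppExports.R'
    'planner.R'
    'rig-geometry.R'
    'pressure-rig.R'
    'synthgen.R'
    'ephys-features.R'
    'psp-detect.R'
    'constats.R'
    'io.R'
    'pipeline.R'
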