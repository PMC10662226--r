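Package: leafPhys
Title: Photosynthetic Capacity, NPQ Kinetics and Reflectance Analysis for
    Excised-Leaf Phenotyping Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing leaf-excision phenotyping experiments on
    C3 and C4 crops. Implements Farquhar-von Caemmerer-Berry A/ci curve
    fitting with bilinear transition-point estimation (Vcmax, Jmax, Rd),
    C4 PEPc initial-slope Vpmax estimation and four-parameter
    non-rectangular hyperbola fitting for Amax, exponential induction and
    relaxation kinetics of non-photochemical quenching, hyperspectral
    reflectance index computation and spectra-wide per-wavelength ANOVA
    with Bonferroni family-wise control, and the treatment-by-time
    repeated-measures inference layer. A seeded synthetic-data generator
    reproduces the full experimental structure (species x treatment x
    time-of-day x replicate) so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
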