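Package: mnps
Title: Simulation and Analysis of Mechano-Node-Pore Sensing Current Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for single-cell mechanophenotyping with mechano-node-pore
    sensing: forward simulation of resistive-pulse current traces from a
    segmented microfluidic channel with known per-cell ground truth;
    moving-average filtering, downsampling and robust baseline estimation;
    detection of cell-transit pulses and decomposition into sizing,
    contraction and recovery subpulses; extraction of mechanical phenotypes
    (free diameter, transit velocity, strain, whole-cell deformability index,
    and viscoelastic recovery time constant via a linearized Kelvin-Voigt
    creep fit with confidence intervals); and cohort-level statistics
    (pooled-variance t tests, Tukey-Kramer all-pairs comparisons, Bonferroni
    correction, notched-median summaries, and post hoc power analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
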