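Package: trpquant
Title: Quantification of Light-Dependent TRP Channel Phosphorylation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for quantifying light-dependent phosphorylation
    of the Drosophila TRP ion channel. Implements label-free LC-MS
    phosphopeptide quantification (charge-state filtering, recursive-median
    run normalization, phosphopeptide eligibility and variant selection,
    relative abundance with unpaired t-tests and significance classes),
    quantitative Western-blot densitometry (phospho/total normalization,
    dilution-series linearity QC, relative phosphorylation versus a
    same-membrane control, time-course scaling), phosphate-occupancy
    estimation from immunoprecipitation signal quadruples together with a
    binomial tetramer co-precipitation bias model and its inverse, and the
    kinase/phosphatase candidate-screen hit caller with rescreen
    confirmation. A synthetic-data module generates feature tables, blot
    panels, IP experiments and screen panels with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
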