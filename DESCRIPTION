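Package: iresscreen
Title: Analysis of High-Throughput RNAi Screens for IRES-Dependent
    Translation Regulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse plate-based RNAi screens that read out
    reporter-mRNA translation by luminescence, modelled on a kinase and
    phosphatase screen against the VEGF IRES. Implements per-plate
    percent-of-control normalization against scrambled-siRNA negative
    controls, triplicate aggregation by medians, cut-off based Up/Down
    calling with at-least-two-siRNA concordance for gene-level hits,
    secondary-screen filtering for IRES specificity (cap-reporter
    channel) and cell viability (ATP channel), efficiency-corrected
    qPCR relative quantification (Pfaffl ratio with a REST-style
    randomization test), and the equal-variance t-test used for ELISA
    comparisons. A seeded synthetic-screen simulator with planted
    regulators provides ground-truth data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    graphics,
    jsonlite,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
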