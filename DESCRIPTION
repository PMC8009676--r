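Package: outflowr
Title: Aqueous Humor Outflow Facility, Trabecular Meshwork Stiffness, and
    Ocular Hypertension Cohort Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of conventional aqueous humor outflow:
    outflow facility estimation from stepped ex vivo eye perfusion records,
    Goldmann-equation accounting of intraocular pressure changes, inverse
    finite-element estimation of trabecular meshwork stiffness from
    Schlemm's canal collapse under pressure, Hertzian extraction of Young's
    modulus from atomic force microscopy indentation curves, outflow-tissue
    morphometry (basement membrane coverage, semi-quantitative extracellular
    matrix grading, region-of-interest fluorescence), and clinical or mouse
    cohort statistics with Tukey-fence outlier screening. A synthetic-data
    module generates every input class with the statistical structure the
    analyses assume, so the whole pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    Matrix,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
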