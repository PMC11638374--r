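Package: chelascreen
Title: Competitive Spectrophotometric Screening of Calcium and Magnesium Chelation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for competitive indicator-displacement
    screening of calcium and magnesium chelators with the metallochromic indicator
    o-cresolphthalein complexone on 96-well microplates. Provides a mass-action
    equilibrium speciation solver with pH-conditional formation constants, a
    synthetic-data generator for spectra, calibration ladders, chelation titration
    plates and impedance aggregometry traces, readers and writers for long-format
    plate data, optimal-wavelength selection by linearity and sensitivity,
    t-test based limit-of-detection estimation, chelation-percentage computation,
    logistic chelation-curve fitting with stoichiometry inference and four-tier
    potency classification, pKa structure-activity regression, and quantification
    of platelet-aggregation inhibition by calcium sequestration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
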