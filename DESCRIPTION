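Package: cscdrift
Title: Kinetics of Cancer Stem Cell Ratio Drift in Long-Term Sphere Culture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the drift of the cancer stem cell (CSC) fraction in
    long-term non-adherent sphere culture with a two-compartment linear
    growth/interconversion ODE. Provides the closed-form solution, the
    Riccati dynamics of the differentiated-to-CSC ratio and its limiting
    value, adaptive Metropolis-Hastings estimation of the four rate
    parameters from ratio time courses, standardized local-sensitivity
    analysis of the sum-of-squared-deviations design function with one-way
    ANOVA and Tamhane's T2 comparisons, and a synthetic time-course
    generator for end-to-end validation. Ships the MCF-7 mammosphere
    CD44+CD24-/low time course used throughout as a packaged fixture.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
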