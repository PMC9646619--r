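Package: wheatphys
Title: Wheat Leaf Photosynthesis, Mesophyll Conductance and Factorial
    CO2-by-Heat-Stress Experiment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing leaf gas exchange of wheat grown under
    elevated CO2 and heat stress: a forward Farquhar-von Caemmerer-Berry
    (FvCB) photosynthesis model with finite mesophyll conductance and
    Arrhenius, peaked-Arrhenius and Q10 temperature scaling; mesophyll
    conductance estimation from concurrent 13CO2/12CO2 carbon isotope
    discrimination with ternary corrections; A-Ci curve fitting with
    measured mesophyll conductance and dark respiration held fixed;
    temperature-response fitting with closed-form optima; a seeded
    synthetic generator for a full factorial cultivar x CO2 x heat-stress
    glasshouse experiment; and treatment-effect analysis (percent changes
    with bootstrap intervals, factorial ANOVA, Tukey letter ranking).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
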