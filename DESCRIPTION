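Package: drypom
Title: Thin-Layer Drying Kinetics and Quality Analysis of Fruit Pomace
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for convective drying of fruit pomace as a
    fiber-rich functional ingredient. Converts raw weighing series into
    moisture-ratio and drying-rate curves, fits the classical thin-layer
    drying models (Page, Modified Page, Henderson-Pabis, Logarithmic,
    Midilli) by bounded multi-start nonlinear least squares and ranks them
    with a small-sample corrected Akaike criterion, estimates effective
    moisture diffusivity by the Fick slab slope method with a geometric
    correction, derives Arrhenius activation energy, fits four-parameter
    logistic dose-response curves for antioxidant IC50 values, and compares
    treatments with one-way ANOVA and Tukey compact letter displays. A
    seeded synthetic-data generator emulates the full experimental protocol
    so every stage is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite,
    optparse
Config/testthat/edition: 3
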