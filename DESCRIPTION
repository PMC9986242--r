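Package: biosorb
Title: Taguchi Design Analysis and Adsorption Isotherm and Kinetic
    Modelling for Dye Biosorption
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing batch dye-biosorption experiments:
    construction and verification of five-level Taguchi orthogonal arrays,
    larger-is-better signal-to-noise analysis with response tables,
    additive main-effects prediction and balanced main-effects ANOVA;
    batch mass-balance quantities (removal percentage, sorbed capacity,
    Langmuir separation factor); linearized and nonlinear fitting of
    Langmuir, Freundlich and Temkin equilibrium isotherms; pseudo-first-
    and second-order, Elovich and Weber-Morris intraparticle-diffusion
    kinetics with model comparison; and seeded synthetic-data generators
    for designed experiments, isotherm batches and uptake time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    ggplot2
Config/testthat/edition: 3
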