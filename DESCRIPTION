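Package: metaburden
Title: Size-Structured and Pressure-Mediated Models of Metastatic Colonization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for confronting the standard (independent-growth) theory of
    metastatic colonization with macro-metastasis size distributions, and for
    quantifying mechanical tumour-tumour interactions. Implements the
    size-structured dissemination-and-growth model of the metastatic
    population under a Gomp-Exp growth law (closed-form characteristics,
    FFT-accelerated burden computation, inhomogeneous-Poisson per-animal
    simulation, lognormal population variability), population fitting of
    growth and dissemination parameters from longitudinal cohort tables, a
    two-dimensional pressure-mediated tumour growth model (Darcy flow,
    pressure-inhibited proliferation, WENO5 advection with Strang splitting),
    interaction and merging experiments, and synthetic-data generators that
    emulate GFP-tracking cohorts and MRI-derived lesion tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
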