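Package: jointdfe
Title: Joint Distribution of Fitness Effects Inference from Two-Population
    Allele Frequency Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the joint distribution of fitness effects (DFE) of new
    deleterious mutations between two diverged populations from the joint
    allele frequency spectrum. Provides a finite-difference diffusion engine
    for expected two-population spectra under isolation-with-migration
    demographic models with selection and dominance, parametric joint-DFE
    models (lognormal and gamma mixtures, bivariate lognormal), caching of
    spectra over a grid of selection coefficients, Poisson random field
    composite-likelihood fitting of demographic and DFE parameters including
    the DFE correlation, uncertainty quantification via the Godambe
    information matrix, and a simulation harness for precision and
    robustness studies. A discrete Wright-Fisher oracle is included for
    validation of the diffusion engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    generics,
    ggplot2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
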