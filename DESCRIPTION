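Package: domdfe
Title: Co-Estimation of the Distribution of Fitness Effects and Dominance
    from Outcrossing and Selfing Site Frequency Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Composite Poisson random-field likelihood machinery to
    co-estimate the gamma distribution of fitness effects (DFE) and the
    relationship between dominance (h) and selection (s) of new
    nonsynonymous mutations, by jointly fitting folded site frequency
    spectra from an outcrossing and a highly selfing population.  Includes
    a finite-difference diffusion solver for expected spectra under
    arbitrary selection, dominance, inbreeding and piecewise-constant
    demography; spline-refined (Ne*s, h) lookup grids; an exact small-N
    Wright-Fisher oracle and a forward simulator for calibration of
    likelihood-ratio tests; and a mechanistic expression-cost model of
    dominance that predicts h and s of loss-of-function mutations from
    optimal gene expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    generics,
    rlang,
    Rcpp,
    tibble,
    ggplot2,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
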