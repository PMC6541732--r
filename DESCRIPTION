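Package: cliffcensus
Title: Census Estimation for Plants on Inaccessible Cliffs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating plant population sizes on inaccessible rocky
    cliffs from grid-cell telescope censuses. Implements observer correction
    factors estimated from paired low/high-magnification counts,
    maximum-likelihood fitting of Geometric, Poisson and Negative Binomial
    models to per-cell counts with chi-square goodness of fit and AIC/BIC
    model ranking, graphical model diagnostics (CDF, PP and QQ series), and a
    minimum-sampling-effort analysis that subsamples grid cells at decreasing
    fractions and attaches maximum-likelihood and simple-bootstrap confidence
    intervals to the expanded population total. A synthetic-data generator
    with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
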