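Package: evopann
Title: EVOP Factorial Design and Neural-Network Surrogate Optimization of
    Fermentation Media
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evolutionary-operation (EVOP) factorial screening of
    solid-state fermentation media and surrogate-based optimization of the
    response surface.  Implements the three-variable 2^3 EVOP worksheet with
    centre replicates, the classical effect and error-limit statistics with a
    shift/stop decision rule, two response-surface surrogates (an ordinary
    least-squares quadratic-in-pH polynomial and a 3-10-1 feed-forward network
    trained by Levenberg-Marquardt with restarts), constrained grid-search
    optimization of predicted enzyme yield, and a synthetic-data generator for
    noisy worksheets and full multi-phase EVOP campaigns with known ground
    truth.  Ships the alkaline-protease screening dataset (wheat bran plus
    soybean meal substrate, Rhizopus oryzae) used throughout the examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm
Config/testthat/edition: 3
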