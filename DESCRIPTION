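Package: lcscreen
Title: In Silico Screening of Reversed-Phase Liquid Chromatography Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Response-surface retention-time models over mobile-phase pH and
    gradient time for known small molecules, with the polynomial equation
    selected per compound from its pKa. Model error is propagated as Student-t
    Monte-Carlo draws of retention time, from which three screening criteria
    are computed over a condition grid: baseline separation of the critical
    pair, sensitivity of that separation to the experimental parameters, and
    analysis time. The criteria are combined into a weighted geometric-mean
    desirability index, made robust to the choice of criterion weights by
    Dirichlet weight sampling, and candidate chromatographic conditions are
    selected as connected high-probability regions of the grid together with
    global and largest-region optima. Includes a synthetic retention-data
    generator (sigmoidal pH dependence around a pKa, linear gradient-time
    effect on log retention, multiplicative noise) so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
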