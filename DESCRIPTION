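Package: shellont
Title: Ontogenetic Shell Shape Trajectories and Adult-Size Thresholds in Turtles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric-morphometric analysis of ontogenetic shell shape change
    from 3D landmark configurations. Provides Generalized Procrustes Analysis,
    permutation-based (residual-randomization) allometric regression with
    common allometric component (CAC) and PredLine shape proxies, Gompertz
    shape-growth curve fitting, two estimators of the minimum carapace length
    at which a species attains its adult shell shape (asymptote confidence
    bound and 85%-of-shape-distance), three-stage ontogenetic clustering, and
    stage-wise morphological disparity (sum of ranges, Procrustes variance)
    with bootstrap, rarefaction, and Zou's overlapping confidence-interval
    test. A synthetic landmark growth-series generator with analytic ground
    truth supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
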