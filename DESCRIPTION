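Package: oculomem
Title: Decoding Working-Memory Contents from MEG and Gaze with Eye-Movement Confound Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multivariate decoding of orientation working-memory
    contents from magnetoencephalography (MEG) and gaze-position epochs, and
    for studying how small stimulus-specific eye movements confound such
    decoding. Implements a regularized multi-class Gaussian probabilistic
    classifier with temporal generalization, an inverted (forward) encoding
    model with von Mises orientation channels and a circular decoding
    statistic (the V-test rho), cluster-based sign-flip permutation tests, a
    weighted up/down adaptive staircase, and a synthetic MEG + gaze data
    generator that reproduces the eyeball-dipole confound mechanism together
    with a confound-free functional localizer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
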