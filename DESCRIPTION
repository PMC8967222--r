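Package: tidysmt
Title: Single-Molecule Tracking Analysis of Nuclear Protein Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing live-cell single-molecule tracking (SMT) of
    nuclear proteins such as transcription factors. Provides a synthetic
    trajectory generator (multi-state diffusion with confinement, motion blur,
    localization noise and photobleaching), spot detection and optimal
    frame-to-frame linking, classification of trajectories into diffusive
    states by perturbation expectation-maximization with BIC model selection,
    posterior-weighted mean-squared displacement curves, bound/confined/free
    fraction summaries, and photobleaching-corrected residence-time analysis
    with power-law dwell fitting. All results are returned as tibbles or
    broom-compatible model objects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
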