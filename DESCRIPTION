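Package: sushibelt
Title: Sushi-Belt Models of Microtubule Cargo Transport in Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses the 'sushi-belt' picture of
    microtubule-based cargo transport in neuronal morphologies. Provides
    stochastic single-particle random walks with run-length memory and
    moment-matched coarse-graining to mass-action rate constants; a
    deterministic mass-action compartmental model on arbitrary dendritic
    trees (exact linear evolution, steady states, delivered distributions,
    relaxation timescales); demand-driven trafficking and detachment
    strategies (demand-dependent trafficking, demand-dependent detachment,
    interpolated mixtures, tuned anterograde bias, geometry-preserving rate
    scaling); and speed-precision-efficiency tradeoff metrics and sweeps.
    Morphologies are read from SWC reconstructions or built synthetically;
    all containers are tidy tibbles so results chain with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
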