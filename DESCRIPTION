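Package: smfret
Title: Simulation and Kinetic Analysis of Single-Molecule FRET Trajectories
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying protein-DNA kinetics from two-color
    single-molecule FRET trajectories recorded on surface-tethered DNA.
    Covers FRET-population classification by three-Gaussian mixture fits
    with intersection thresholds, fraction-unwound time courses fitted to a
    one-phase association model, maximum-likelihood two-state hidden Markov
    idealization of dynamic traces, dwell-time survival (1-CDF) analysis
    with single-exponential rate fits, and decomposition of composite exit
    rates into dissociation and sliding-clamp branches from branch counts.
    Includes a seeded generator of synthetic donor/acceptor intensity
    trajectories emulating CRISPR-dCas9 DNA-unwinding snapshot experiments
    and MutS mismatch-binding movies, for end-to-end parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    graphics,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    patchwork,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
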