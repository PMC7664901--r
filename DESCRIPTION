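Package: xbridge
Title: Bottom-Up Mechanokinetic Modelling of Actomyosin Motor Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating muscle-like actomyosin ensembles from
    single-molecule properties. Implements a seven-state cross-bridge cycle
    with strain-dependent transition rates constructed from free-energy
    diagrams under exact detailed balance, linear or Kaya-Higuchi-type
    nonlinear cross-bridge elasticity, a Huxley/Hill-formalism steady-state
    solver for force-velocity and power curves, an exact event-driven
    (Gillespie) Monte Carlo engine for small and half-sarcomere-scale
    ensembles with quasi-static filament mechanics, and post-processing
    utilities including step detection and clustering in displacement
    records, isometric force-rise fitting, exact small-sample Spearman
    correlation, and parameter-sweep experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
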