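Package: cemasim
Title: Agent-Based Simulation of Cross-Embryo Morphogenetic Assistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cohorts of developing embryos as elementary cellular
    automata solving the majority (density classification) problem under the
    Gacs-Kurdyumov-Levin (GKL) rule, coupled on a two-dimensional dish grid by
    stochastic teratogen-like noise, health/stress broadcasting and supportive
    inter-embryo signaling (cross-embryo morphogenetic assistance, CEMA).
    Includes a batch experiment harness for survival-versus-cohort-size sweeps
    and signaling ablations with replicate statistics, plus quantification of
    injury-induced calcium waves from fluorescence image stacks (baseline
    normalization, sustained transfer detection, wave speeds, kymographs)
    validated against a synthetic movie generator with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
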