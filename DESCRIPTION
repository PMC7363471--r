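Package: interictal
Title: Whole-Brain Network Modelling of Interictal Resting-State Dynamics in Epilepsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates large-scale brain network activity in epilepsy during the
    interictal (between-seizure) resting state. Each region is a hybrid neural
    mass mixing an Epileptor subpopulation (epileptiform discharges and
    seizures, controlled by the epileptogenicity x0) with a supercritical-Hopf
    oscillator subpopulation (physiological ~10 Hz resting activity, controlled
    by the bifurcation parameter a), coupled over a structural connectome by
    permittivity and diffusive coupling and integrated with a stochastic Heun
    scheme. Includes the Balloon-Windkessel haemodynamic forward model with
    fMRI-like post-processing, five resting-state functional-connectivity
    observables (static Pearson correlation, functional connectivity dynamics,
    Kuramoto coherence and metastability, multiscale sample entropy), a
    composite Global Similarity fitting score, and scripted parameter-sweep
    experiments (working point, interictal spiking, hyperexcitability) with
    rank-sum statistics, all runnable on synthetic connectomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
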