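Package: glucoExchange
Title: Hydroxyl-Proton Chemical Exchange Lineshape Simulation and Fitting for Glucose NMR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of chemical-exchange broadened 1H NMR
    spectra of glucose hydroxyl protons exchanging with water. Provides
    multi-pool exchange models for the alpha/beta anomer hydroxyl sites,
    forward simulation of exchange-broadened spectra in extended Liouville
    space (Bloch-McConnell dynamics), adaptive Metropolis MCMC fitting of
    exchange rates and chemical shifts with symmetrized 95 percent credible
    intervals, Eyring transition-state extrapolation of exchange rates over
    temperature with first-order uncertainty propagation, and virtual CPMG
    experiments (exchange relaxivity and CPMG-filtered spectra). A synthetic
    data generator produces temperature series with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    pracma,
    minpack.lm
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'constants.R'
    'exchangeModels.R'
    'eyring.R'
    'mcmc.R'
    'spectrumSim.R'
    'pipeline.R'
    'syntheticData.R'
    'virtualExperiments.R'
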