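Package: firingclamp
Title: Firing-Clamp Estimation of Excitatory and Inhibitory Synaptic
    Conductances
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the firing-clamp
    protocol, a dynamic-clamp recording mode in which constant-rate probe
    spikes are evoked by a meander-shaped current whose hyperpolarizing
    phase ends when the membrane voltage crosses a reset value.  Two
    characteristics of each probe cycle, the mean subthreshold potential
    and the positive-pulse response voltage, are inverted through a
    least-squares calibration surface to recover the total synaptic
    current and conductance, which known reversal potentials then split
    into excitatory and inhibitory components.  Includes a
    single-compartment conductance-based neuron simulator, the protocol
    engine, calibration and closed-form inversion routines, synthetic
    synaptic-input scenario generators, and reference multi-trial
    continuous current-clamp and hyperpolarizing pulse-probe estimators
    for cross-method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
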