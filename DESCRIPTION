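Package: magnoise
Title: Intrinsic Magnetization Noise of Superparamagnetic Field Amplifiers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of a hybrid cryptochrome/magnetite model of the
    avian magnetic compass. Models a single-domain superparamagnetic nanoparticle
    as a magnetic-field amplifier (Curie susceptibility and relative permeability),
    derives its intrinsic magnetization noise and noise-equivalent power from the
    fluctuation-dissipation theorem (Lorentzian moment spectrum, Kramers-Kronig
    consistent generalized susceptibility), compares radical-pair internal hyperfine
    field spectral densities with experimental broadband radio-frequency noise
    fields, and sweeps the volume-relaxation-time plane to test whether a particle
    can simultaneously amplify enough and stay quiet enough. Includes seeded
    stochastic simulators (random telegraph and Ornstein-Uhlenbeck moment dynamics)
    with autocorrelation, Welch spectral-density and linear-response estimators
    that validate the analytic machinery end to end. Internal units are Gaussian
    CGS; laboratory-facing interfaces accept nanotesla and kilohertz.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
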