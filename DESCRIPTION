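Package: kndysim
Title: Conductance-Based Modelling and Analysis of Arcuate Kisspeptin (KNDy) Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Hodgkin-Huxley style conductance-based model of the arcuate
    kisspeptin (Kiss1/KNDy) neuron with twelve ionic currents, together with
    the quantitative electrophysiology pipeline used to calibrate and
    interrogate it: in-silico voltage- and current-clamp protocols, Boltzmann
    activation/inactivation fits, drug-subtraction current isolation,
    M-current deactivation analysis, slow-EPSP and burst metrics, rheobase and
    F-I curves, firing-pattern classification, two-parameter conductance
    regime maps, per-channel conductance calibration against current-density
    targets, qPCR standard-curve efficiency and comparative delta-delta-CT
    quantification, and seeded synthetic-data generators for voltage-clamp
    cohorts, spike trains and CT pools. Two physiological parameterizations
    (ovariectomized, and ovariectomized with positive-feedback estradiol) ship
    as editable presets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
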