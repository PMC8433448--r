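Package: cpgpace
Title: Robust Coupled Spiking Neural Oscillators for Adaptive Cardiac Pacemaking
Version: 0.1.0
Authors@R:
    person("cpgpace", "developers", email = "cpgpace@example.org", role = c("aut", "cre"))
Description: Simulates central-pattern-generator networks of adaptive
    exponential integrate-and-fire neuron populations on a mismatched
    (device-variability) substrate, emulating a mixed-signal neuromorphic
    processor in software.  Provides the semi-automatic tuning procedures
    that set the oscillation frequency and inter-oscillator phase shifts of
    a three-oscillator cardiac pacemaker network, an explicit
    period-to-current calibration, and a closed-loop respiratory feedback
    pipeline modelling respiratory sinus arrhythmia: breathing-phase
    segmentation, breathing-coefficient computation, quadratic R-R interval
    models, inhibitory rate calibration, and deterministic rate-to-spike
    encoding.  Includes a synthetic generator for dog-at-rest respiration
    and R-R interval data used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
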