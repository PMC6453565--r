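Package: ofctrack
Title: Optimal Feedback Control Simulation and Analysis of Movement Intermittency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates visuomotor tracking with a discrete-time optimal
    feedback controller (steady-state Kalman state estimation, forward
    projection over the intrinsic loop delay, LQR-derived
    proportional-integral control, and Smith-Predictor compensation of
    feedback delay), together with synthetic motor-cortex local field
    potentials driven by the estimator's synaptic inputs. Provides the
    complete analysis chain for movement intermittency: cursor
    angular-velocity power spectra, submovement-peak extraction and
    period-versus-delay regression, perturbation transfer functions and
    intrinsic phase delays, controller-architecture inference, Welch
    power/coherence/imaginary-coherence spectra, submovement-triggered
    averaging, and principal-component trajectories of multichannel field
    potentials.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
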