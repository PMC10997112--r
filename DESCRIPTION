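Package: walkstab
Title: Stability of Inverted-Pendulum Walking with Foot-Placement Feedback
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models bipedal gait as a linearized single-link inverted
    pendulum whose foot placement is chosen at each step by a
    proportional-derivative feedback law on the midstance center-of-mass
    state. Provides exact closed-form simulation of the hybrid dynamics,
    computation of periodic walking orbits, step-to-step error-propagation
    (transition matrix) analysis with a closed-form triangular stability
    region in control-gain space, cadence sweeps of the region limits,
    regression-based estimation of the control gains from step-level data,
    and a synthetic noisy-gait generator for validating the estimator by
    parameter recovery. Includes a small command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), deSolve, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
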