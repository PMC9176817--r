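Package: socmove
Title: Approximate Stochastic Optimal Control of Muscle-Driven Movement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gaussian approximation of stochastic optimal control for nonlinear
    neuromusculoskeletal models: mean-state dynamics with Lyapunov covariance
    propagation, chance-constrained task specifications, and co-optimization of
    feedforward muscle excitations and linear feedback gains for minimum expected
    effort. Ships two instantiations -- an inverted-pendulum standing-balance model
    on a stochastically perturbed platform with proprioceptive and vestibular
    feedback, and a planar two-link, six-muscle reaching model with end-effector
    feedback under four task conditions -- together with Hill-type rigid-tendon
    muscle mechanics (optionally augmented with activation-dependent short-range
    stiffness), Euler-Maruyama Monte-Carlo forward simulation, and analytic
    validation fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
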