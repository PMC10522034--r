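Package: vmadapt
Title: State-Space Models of Visuomotor Adaptation Under Sensory Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, fitting and statistical analysis of trial-by-trial
    visuomotor rotation learning when visual feedback is delivered with graded
    uncertainty at movement midpoint and/or endpoint. Implements joint
    feedforward-adaptation and feedback-integration state-space models in five
    uncertainty-scaling families (error-, retention-, bias-, state-aim- and
    output-aim-scaling), in one-state, two-state and non-negative variants;
    generators for the corresponding experiment designs and for synthetic
    participants; kinematic marker extraction from 2-D reach trajectories;
    per-participant model fitting by bounded differential evolution with BIC
    model comparison; and backward-difference-coded regression analyses of
    feedforward adaptation and feedback integration, including relative
    importance decomposition and adaptation-versus-washout difference scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
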