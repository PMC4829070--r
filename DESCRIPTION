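Package: pgtsim
Title: Prompt Gamma-Ray Timing Simulation and Proton Range Verification
Version: 0.1.0
Authors@R: person("OncoRange", "Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulator and analysis toolkit for prompt gamma-ray timing (PGT),
    an uncollimated range-verification technique for proton therapy. Provides
    continuous-slowing-down-approximation (CSDA) proton transport through
    heterogeneous layered phantoms, analytic and Monte Carlo PGT timing
    spectra with bunch-period wrap-around and accelerator phase drifts,
    time-to-depth inversion with solid-angle and time-of-flight corrections,
    trailing-edge range-shift detection with bootstrap confidence intervals,
    and detector-physics models: scintillator energy and timing resolution
    fits, a background-suppression figure of merit, photon attenuation
    tables, Compton kinematics with cone backprojection, and Anger-logic
    flood maps for block detectors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
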