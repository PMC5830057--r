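Package: bmisim
Title: Simulation of Neuronal Ensemble Properties and Direction Decoding
    for Intracortical Brain-Machine Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Synthesizes directionally tuned motor-cortical ensembles with
    controlled signal-to-noise ratio, preferred-direction geometry,
    well-/poorly-tuned mixtures and gradual preferred-direction drift;
    generates Poisson spike counts from cosine tuning curves driven by a
    smooth 2D random-pursuit trajectory; decodes movement direction with
    the population vector algorithm, the optimal linear estimator and the
    Kalman filter; and evaluates decoders with circular statistics
    (angle differences, Rayleigh test, Watson's two-sample U2) across
    seeded Monte-Carlo sweeps of ensemble properties.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
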