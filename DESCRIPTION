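Package: cortexloop
Title: Closed-Loop Widefield-Calcium Brain-Machine Interface Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates and analyses a closed-loop brain-machine interface in
    which two cortical regions' widefield calcium signals drive a discrete
    sensory feedback cursor. Provides a seeded synthetic-data generator
    (correlated region traces with calcium-indicator dynamics, pixel movies,
    an exploring-then-exploiting agent, cursor-tuned Poisson spiking
    populations), the online decoder (sliding-percentile dF/F, baseline
    calibration, visual position and auditory frequency transforms, chance-rate
    estimation by spontaneous replay), a trial engine with hold detection and
    control conditions (random reward, random feedback, passive playback,
    ghost-decoder evaluation), behavioral and spectral-entropy metrics,
    pixelwise cortical maps (activation, seed correlation, spike affiliation),
    single-unit cursor-tuning analyses, and a correlation-template population
    classifier with cross-validated shuffle controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
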