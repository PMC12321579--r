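Package: interictal
Title: Interictal Dynamics, Event Detection and Closed-Loop Stimulation
    Simulation for Epilepsy Electrophysiology
Version: 0.9.0
Authors@R:
    person("Ingrid", "Halvorsen", email = "ingrid.halvorsen@posteo.net",
           role = c("aut", "cre"))
Description: Tools for analysing interictal dynamics in multichannel local
    field potential (LFP) recordings from focal-epilepsy models: detection of
    interictal epileptiform discharges (IEDs), sleep spindles and cortical
    DOWN states; cross-correlogram coupling statistics with a
    convolution-method baseline and Poisson confidence bounds; multitaper
    coherence and wavelet spectrograms; a detection-free LFP gradient
    sharpness ("epileptogenicity") index; peri-event single-unit modulation
    statistics; and a causal emulator of an IED-triggered closed-loop
    stimulation controller.  A seeded synthetic-session generator emulating
    kindling progression provides ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
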