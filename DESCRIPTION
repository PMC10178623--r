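Package: ffrdev
Title: Developmental Analysis of Frequency-Following and Cortical Auditory Responses
Version: 0.1.0
Authors@R:
    person("FFR", "Pipeline Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for developmental auditory
    electrophysiology with lexical-tone stimuli. Generates synthetic
    longitudinal EEG cohorts (phase-locked frequency-following responses and
    slow cortical responses with a dominant P1 positivity), preprocesses raw
    sweeps to quality-controlled averages (zero-phase Butterworth filtering,
    resampling, epoching, amplitude-based artifact and block rejection),
    computes frequency-following response metrics (signal-to-noise ratio,
    autocorrelogram pitch strength, spectral band powers, intertrial phase
    coherence pitch tracking), detects the P1 peak of long-latency responses,
    performs per-month bootstrapped linear support-vector-machine tone
    decoding with permutation nulls, and fits the mixed-effects and
    rank-based group statistics used to characterise maturation of the two
    response classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nlme,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
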