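Package: icassr
Title: Inferior-Colliculus LFP Analysis: Transient Evoked Responses, Auditory
    Steady-State Responses, and Freezing Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing local field potentials (LFP) recorded from
    the inferior colliculus during auditory stimulation. Synthesizes transient
    tone-burst trains and amplitude-modulated (AM) tones with reference sync
    tracks as stereo WAV; recovers stimulus event timing from recorded
    reference tracks; computes Welch power spectral densities,
    magnitude-squared coherence against a reference sine, short-time Fourier
    transform band power, transient evoked-response latency and amplitude,
    minimum-variance analysis-window election, conditioned-stimulus
    baseline-normalized steady-state power, and freezing-behavior scores.
    Includes a synthetic LFP session generator with known ground truth
    (1/f-colored background, phase-jittered entrained components, evoked
    kernels, movement artifacts) for validating every analysis stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'wav.R'
    'stimulus.R'
    'detect.R'
    'spectral.R'
    'synthetic.R'
    'transient.R'
    'assr.R'
    'behavior.R'
    'session_io.R'
    'pipeline.R'
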