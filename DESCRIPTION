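Package: twitchbci
Title: Transient Target Stimuli in Steady-State Somatosensory Evoked
    Potential Brain-Computer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the interplay between steady-state
    somatosensory evoked potentials (SSSEPs) and transient target stimuli
    ("twitches") embedded in repetitive tactile stimulation, as used in
    hybrid tactile brain-computer interfaces.  Provides stimulus and
    session-schedule generation, a synthetic multichannel EEG generator
    with controllable SSSEP, P300 and twitch-locked blocking effects,
    lock-in amplifier (LAS) amplitude demodulation in standard and fast
    settings, P300 epoch averaging, screening tuning-curve maps with
    bootstrap confidence intervals, shrinkage-regularized linear
    discriminant classification with repeated stratified
    cross-validation, exact binomial chance levels, and a Monte-Carlo
    permutation test for twitch-locked SSSEP attenuation ("blocking").
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
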