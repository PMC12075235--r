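Package: vigiscore
Title: Semi-Automatic Vigilance-State Scoring of Rodent EEG/EMG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Rule-based semi-automatic scoring (SAS) of continuous rodent
    electrophysiology into seven vigilance states (three awake substates, REM,
    and three graded non-REM substates) plus a noise label, using fixed
    frequency-profile rules on per-epoch FFT power spectra gated by an
    EMG muscle-tone change-point segmentation. Includes label analytics
    (state proportions, transition pairs, hourly and cumulative
    distributions, correlograms, Bonferroni difference-wave tests), a
    per-state validation battery (time-averaged wavelet coherence,
    permutation-normalised phase-amplitude coupling, detrended fluctuation
    analysis, functional excitation-inhibition ratio, aperiodic 1/f
    exponent, sleep-spindle detection), a synthetic EEG/EMG recording
    generator with known ground truth, and EDF/CSV input-output with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
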