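Package: fretfp
Title: Fiber-Photometry Analysis of FRET Metabolite Sensors During
    Epileptic After-Discharges
Version: 0.1.0
Authors@R:
    person("Maintainer", "fretfp", email = "fretfp@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing in vivo fiber-photometry recordings of
    FRET-based metabolite biosensors (a neuronal ATP sensor of the ATeam
    family and an astrocytic pyruvate sensor) during electrically evoked
    epileptic after-discharges.  Includes demultiplexing of
    time-division ("gallop" mode) excitation into 1 Hz per-channel
    fluorescence traces, artifact correction by the ratio and difference
    methods, Texas Red blood-volume detrending, EEG after-discharge
    detection, event-feature extraction (peaks, second-derivative
    onsets, triphasic segmentation, cumulative signals), summary
    statistics, and a biophysical forward simulator (Hill-binding
    sensors, blood-volume shadowing, pH quenching, multiplexed PMT
    voltages, EEG) that provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
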