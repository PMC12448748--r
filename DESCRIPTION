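Package: tbsmod
Title: Single-Neuron Modulation Analysis for Intracranial Theta-Burst Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Epoch-based analysis of single-unit firing-rate modulation by
    intracranial theta-burst stimulation (TBS): peri-stimulation spike-count
    contrasts with Wilcoxon signed-rank statistics against a shuffled
    epoch-label permutation null, waveform-morphology cell-type clustering,
    pseudo-population PCA trajectories, multiunit threshold-crossing
    analysis, recognition-memory d-prime statistics, and robustness controls
    (inclusion-threshold sweep, artifact dropout, detection-power
    simulation). Includes a synthetic-data generator emulating the trial
    structure of a TBS recognition-memory experiment for calibration and
    power analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
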