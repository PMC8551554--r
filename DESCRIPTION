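Package: eegsourcenet
Title: Source-Space EEG Brain Network Analysis with Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Pipeline for resting-state EEG brain-network analysis in source
    space: weighted minimum-norm inverse solutions, parcellation to a 68-region
    cortical atlas, Welch band power spectra, phase-locking-value (and phase lag
    index) connectivity in canonical frequency bands, weighted graph metrics
    across proportional sparsity thresholds, and permutation-based group
    statistics including the network-based statistic with false-discovery-rate
    control. Includes a synthetic cohort generator with planted spectral and
    phase-coupling effects (closed-form expected phase locking via modified
    Bessel ratios) emulating a patient/control study with a paired
    stimulation-on/off condition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
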