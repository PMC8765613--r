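Package: odorosc
Title: Sniff-Aligned Oscillation Analysis for Intracranial Olfactory Recordings
Version: 0.1.0
Authors@R:
    person("Piriform", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for odor-evoked local field potential oscillations
    aligned to sniff onset: zero-phase FIR preprocessing, a logarithmic Hilbert
    filter bank, permutation-normalized spectrograms, cluster-mass timing
    statistics, respiratory-phase circular statistics, accuracy-linked
    resampling and linear-SVM decoding, and Kullback-Leibler phase-amplitude
    coupling with circular-shift and trial-shuffle nulls. Includes a synthetic
    sniff-locked LFP generator with ground truth for parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
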