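Package: flytrace
Title: Calcium-Imaging Analysis of Visual Interneuron Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-photon calcium-imaging recordings of
    Drosophila visual interneurons under bath pharmacology and full-field flash
    stimulation. Reads multi-page TIFF movie stacks, performs rigid in-plane
    motion correction by phase correlation, discovers terminal regions of
    interest by a global-median intensity threshold followed by k-means
    activity clustering and a watershed split, and extracts per-ROI
    fluorescence traces. Traces are notch-filtered (slow brain-motion
    oscillation, stimulus-response bands), converted to dF/F under bath or
    visual baseline rules, and averaged into stimulus-locked epoch responses
    from which transient kinetics (peak and trough size, 90-10 decay and 10-90
    rise times, exponential rate constants, secondary responses) are measured.
    Group comparisons use two-tailed Wilcoxon rank-sum tests, two-way
    repeated-measures ANOVA and Sidak-adjusted pairwise tests. A synthetic
    movie and trace generator with exported ground truth makes every stage
    testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
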