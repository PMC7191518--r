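Package: contrastgain
Title: Contrast Gain Control Analysis for Auditory Cortex Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying contrast gain control in auditory cortex:
    synthesis of dynamic random chord (DRC) stimuli with controlled
    spectrotemporal contrast, extraction of analog multiunit activity and
    local field potentials from extracellular voltage traces, estimation of
    space-time separable spectrotemporal receptive fields by alternating
    least squares, nonparametric gain and contrast-gain statistics under
    optogenetic manipulation, photo-tagging classification of putative
    parvalbumin-positive interneurons, and intracellular whole-cell analysis
    including access-resistance compensation and Ohmic input-conductance
    estimation. A synthetic-data module generates extracellular and
    intracellular recordings with known ground truth so that every analysis
    stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
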