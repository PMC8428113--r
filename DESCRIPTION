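Package: syncdecode
Title: Connectivity-Based Decoding of Auditory Working Memory Content
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how the content of
    auditory working memory can be decoded from interregional phase
    synchronization. Generates dynamic ripple sound stimuli, simulates
    adaptive psychophysical staircases, and synthesizes multi-subject
    cohorts of cortical sub-region time series with planted
    condition-specific phase coupling, impulse-dependent power patterns,
    and linked behavioral performance. Provides Morlet wavelet
    time-frequency decomposition, multitaper power spectra,
    imaginary-coherence connectivity features, cross-subject and
    within-subject support-vector-machine decoding, support vector
    regression of behavior, and permutation-based inference with
    maximum-statistic family-wise error control and linear mixed-effect
    contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    lme4,
    lmerTest,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
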