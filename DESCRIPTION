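Package: singletone
Title: Auditory Attentional Capture by Timbre Singletons: Stimuli,
    Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the auditory additional-singleton paradigm with
    timbre-defined singletons. Synthesizes harmonic complex tones whose
    brightness is controlled through the spectral centroid (spectral
    slope exponent) and whose roughness is controlled through 50 Hz
    amplitude-modulation depth; builds jnd-scaled feature ladders and
    exactly balanced trial plans for five experiment designs; simulates
    observers whose reaction times follow a linear, sign-symmetric,
    feature-additive attentional-capture law; and runs the matching
    analysis pipeline (2-SD trimming, correct-only reaction times,
    LISAS, paired t-tests with Holm correction, power analysis, and the
    regression of reaction-time cost on perceived feature deviation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
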