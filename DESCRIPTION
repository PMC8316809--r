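Package: picosocial
Title: Growth-Strategy Modulation of Picoplankton in Response to Conspecific Cues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for batch-culture experiments that
    ask how picoplankton lineages modulate their maximum growth rate in response
    to the presence of non-self conspecifics (their social milieu). Provides a
    synthetic-experiment generator with the full factorial lineage-pairing
    structure of indirect (membrane insert), perceived (supernatant spike) and
    direct (GFP-tagged co-culture) exposure scenarios; threshold gating of
    flow-cytometry-like event tables; exponential growth-rate estimation from
    cell counts; mono- versus mixed-culture response ratios; conversion of
    oxygen-based photosynthesis rates into carbon budgets and surplus
    photosynthate; a regression-to-the-mean null model for the mono- versus
    mixed-culture relationship; and a linear mixed-effects inference layer with
    likelihood-ratio tests and AICc model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
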