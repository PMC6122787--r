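Package: seasonrhythm
Title: Circannual Cosinor Analysis of Cognition, Biomarkers, and Brain Gene Modules
Version: 0.1.0
Authors@R: person("Season", "Rhythm Maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Tools for detecting and quantifying circannual (seasonal) rhythms
    in clinical and molecular data from aging cohorts. Implements free-phase
    single-component cosinor regression with covariate adjustment, nested
    F-tests of rhythmicity, bootstrap confidence intervals for amplitude,
    seasonal logistic models of diagnosis odds (continuous cosine and
    categorical winter/spring contrast with likelihood-ratio tests),
    group-modulated rhythm models, gene co-expression module summarization
    with permutation-based family-wise error control and phase-concordance
    selection, transcription-factor binding-site proximity enrichment, and a
    fully seeded synthetic-cohort generator that emits ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
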