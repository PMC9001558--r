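Package: rivaltact
Title: Event-Locked Analysis of Tactile Influences on Binocular Rivalry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing binocular rivalry button-press records with
    collocated tactile motion stimuli. Provides a stochastic renewal-process
    simulator of rivalry alternations with hazard-modulated tactile
    perturbations, preprocessing of press/release traces (artefact removal,
    axis remapping, dominance statistics), tactile-onset-locked segment
    extraction and congruency classification, binomial random-intercept
    mixed models of switch probability with likelihood-ratio interaction
    tests and response-scale contrasts, normalised congruent-probability
    timecourses with FDR-corrected bin tests and cluster-mass permutation
    testing, and first-switch latency analysis with repeated-measures ANOVA
    (Greenhouse-Geisser correction, Mauchly test, generalized eta squared).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    lme4,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
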