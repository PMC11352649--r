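Package: erdba
Title: Event-Related Deep-Brain Activity and Behavioral Analysis for Missing-Oddball Cued Tapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for missing-oddball cued finger-tapping
    experiments with occipital EEG. Implements the event-related deep-brain
    activity (ER-DBA) method (occipital alpha-2 band power at 32 samples/s,
    stimulus-locked epoching, artifact rejection, grand averaging with SEM
    bands and envelope normalization), a Cz event-related potential (ERP)
    pipeline with late-auditory component and omission-response scoring,
    kernel-density decomposition of bimodal reaction-time distributions into
    proactive and reactive lobes, modified signal-detection-theory indices
    (d-prime and criterion from correct-hit and correct-rejection rates), a
    statistical toolkit (one-way ANOVA with eta-squared, Holm-Sidak step-down
    correction, correlation with ANOVA indices, Welch t-test with post-hoc
    power, sample-size planning), and a synthetic-cohort generator that
    emulates the stimulus sequences, tap behavior and EEG structure the
    analysis assumes, so that every stage is testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
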