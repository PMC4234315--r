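Package: probeERP
Title: Irrelevant-Probe ERP Assessment of Cognitive Workload
Version: 0.1.0
Authors@R:
    person("RIC", "Neuroergonomics Tools", email = "probeerp@example.org",
           role = c("aut", "cre"))
Description: Quantifies cognitive workload during human-machine-interface
    tasks from event-related potentials (ERPs) elicited by task-irrelevant
    auditory probes. Provides a seeded synthetic-session generator
    (continuous EEG with pink-noise and alpha background, eyeblink
    artifacts, probe events, behavioral logs, and questionnaires), EEG I/O
    (EDF and a documented text/binary container), zero-phase Butterworth
    bandpass filtering, epoch extraction with baseline correction and
    threshold artifact rejection, component window-mean amplitude scoring
    (N100, P200, P300, LPP at Fz/Cz/Pz), and the corresponding statistical
    endpoints: two-way repeated-measures ANOVA with Greenhouse-Geisser
    correction, Tukey-adjusted post-hoc workload contrasts, paired t-tests,
    correlations, behavioral summaries, and Likert questionnaire scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
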