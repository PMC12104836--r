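Package: normkit
Title: Normative and Abnormality Mapping of Intracranial EEG
Version: 0.1.0
Authors@R:
    person("normkit", "developers", email = "normkit@example.org",
           role = c("aut", "cre"))
Description: A bedside-to-desktop dataflow for regional normative mapping of
    intracranial EEG (icEEG). Provides constraint-based interictal segment
    selection from annotated exam timelines, electrode-contact localisation to
    nearest same-hemisphere grey-matter parcels, a validated document database
    for cohort metadata, regional log relative band power (log(RBP)) normative
    maps with leave-one-out outlier control, and per-subject z-score
    abnormality maps with the resected-versus-spared distinguishability
    statistic (AUROC). Includes a seeded synthetic-cohort generator (1/f
    signals with band-limited oscillations, line noise, artifact and spiking
    channels; seizure-annotated timelines; toy labelled volumes and resection
    masks) so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
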