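Package: pupilflow
Title: Plugin-Based Workflow Engine for Event-Related Pupillometry
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A lightweight scientific workflow system for event-related
    time-series analysis, with a full processing chain for task-evoked
    pupillometry: a flexible columnar eyetracker-export reader, event
    recoding, blink-gap interpolation with quality criteria, zero-phase
    moving median/mean filtering, epoch extraction with baseline correction
    and per-trial measures, and a studentized two-sample bootstrap test.
    Analyses are organised as ordered sequences of self-describing plugins
    acting on a self-contained study object; studies round-trip through
    shareable archive bundles carrying raw data, workflow settings, plugin
    source snapshots and provenance, identified by deterministic
    content-derived codes and lockable for archival. A synthetic
    eyetracker-data generator emulating a mental-multiplication experiment
    makes every stage testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    ggplot2,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
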