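# Shared fixture builders; everything is generated in code.

toy_channel <- function(values, rate = 50, start = 0, name = "pupil") {
  ts_channel(name, values, rate, start)
}

# A minimal in-memory study: one subject, one eyetracking modality built
# directly (no raw files), ready for the in-place processing stages.
toy_study <- function(values = c(1, NA, 3, 4, 100, 6, 7), rate = 50,
                      events = event_list(), name = "toy") {
  m <- ts_modality(channels = list(pupil = toy_channel(values, rate)),
                   events = events)
  s <- ts_subject("S01")
  s$modalities$eyetracking <- m
  add_subject(ts_study(name), s)
}

toy_pupil <- function(study, subject = 1) {
  study$subjects[[subject]]$modalities$eyetracking$channels$pupil$values
}

# Hand-written combined-dialect file content (the 5-row worked example:
# 50 Hz, an event on the third row).
hand_clearview_text <- function() {
  paste(
    "Timestamp\tGazepointX\tGazepointY\tPupil\tEvent",
    "0\t512\t384\t3.1\t",
    "20\t513\t385\t3.2\t",
    "40\t514\t386\t-1\tstim",
    "60\t515\t387\t3.4\t",
    "80\t516\t388\t3.5\t",
    sep = "\n")
}

# Small simulation config for fast tests.
small_sim_config <- function(...) {
  simulation_config(n_subjects = 2, trials_per_condition = 3, ...)
}

# A ready-to-run small case study (raw files attached, workflow loaded).
small_case_study <- function(seed = 1, bootstrap = FALSE, ...) {
  study <- simulate_study(small_sim_config(...), seed = seed)
  load_workflow(study, shipped_workflow(
    if (bootstrap) "case_study_bootstrap" else "case_study"))
}

fingerprint <- pupilflow:::data_fingerprint
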