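---
title: "Methods: event-related pupillometry workflows in pupilflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-related pupillometry workflows in pupilflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilflow)
```

## What the package models

Task-evoked pupil dilation indexes cognitive load: when a participant
works on a harder problem, the pupil dilates more, peaking a few seconds
after the task begins. pupilflow analyses such recordings with a
lightweight workflow system: a *study* holds subjects (each with raw
eyetracker exports and parsed time-series channels), an ordered list of
configured *plugins*, source snapshots of every plugin, and a provenance
log. Running the workflow applies each stage, in order, to the selected
subjects. Order matters — a median filter before gap interpolation is not
the same analysis as the reverse — so the engine always executes stages
in workflow order, never in selection order.

The reference analysis shipped with the package
(`shipped_workflow("case_study")`) is an event-related pupillometry
pipeline for a mental-multiplication experiment: participants silently
multiply two numbers shown 2 s and 4 s after trial onset, with operand
pairs drawn from 1–9 (easy), 6–14 (medium) or 11–19 (difficult). Harder
problems evoke stronger dilation roughly 6–8 s after onset.

## The five processing stages

1. **Columnar reader** (`core/read_file`). Parses tab-separated
   "combined" exports (gaze x/y, pupil and event labels in one file).
   A column map links columns to channels, declares the timestamp unit,
   and lists the dialect's missing codes (here `-1`), which are mapped to
   `NA` at parse time — no sentinel magnitudes survive into analysis.
   Sampling is modelled as strictly uniform: sample `i` (0-based) lies at
   `start_time + i / sample_rate`, validated against the timestamp
   deltas. Rows with a non-empty event cell become events named by the
   cell value.
2. **Event recoding** (`core/modify_events`). Ordered
   `pattern -> name` rules (first match wins, `*`/`?` wildcards) group
   stimulus triggers into the conditions `easy`, `medium`, `difficult`.
   Times and counts are never altered.
3. **Gap interpolation** (`core/interpolate_gaps`). Blinks and tracking
   loss leave runs of missing samples. A gap is filled only if it is
   *strictly shorter* than `max_gap` (default 5 samples — a 5-sample gap
   stays), has valid samples on both flanks (edge gaps never fill), and
   passes the optional quality criteria: a maximum flank-to-flank jump
   and a valid value range for inserted samples. Methods: nearest
   neighbour, linear (default), or a natural cubic spline. Originally
   valid samples are never modified.
4. **Zero-phase filtering** (`core/filter_moving_average`). A symmetric
   sliding window of `halfwidth` samples each side (default 5, i.e. an
   11-sample window) introduces no phase shift. The case study runs a
   median pass (removing spurious outlier pupil sizes) followed by a mean
   pass (smoothing) with the same window — the single stage setting
   `statistic: median+mean` encodes that two-pass order. Windows shrink
   at the recording edges (no padding, no truncation), preserving trial
   alignment; windows ignore missing values and return missing only when
   entirely missing.
5. **Event-related extraction**
   (`core/event_related_data_extraction`). Trials are segments
   time-locked to condition events. All windows are half-open
   `[start, end)` in seconds, so abutting windows (baseline `[0, 2)`,
   measure `[6, 7)`) never share a sample; events snap to the nearest
   sample at or after their time. Baseline correction is *subtractive*:
   the mean of the trial's non-missing baseline samples is subtracted
   from the whole trial. Per trial, scalar measures over the measure
   window: mean, median, min, max, latency to min/max (from trial start,
   earliest sample on ties) and range. Condition average curves carry a
   pointwise normal confidence band, mean ± z·SE across trials
   (level 0.95 by default). Trials whose window leaves the recording are
   dropped and counted.

A sixth, optional stage (`test/bootstrap`, the shipped example of a
custom plugin) reduces each subject to per-condition mean trial values,
draws the per-subject line plot, and tests easy vs difficult with the
bootstrap below.

## The bootstrap test

`bootstrap_pvalue(x, y, n_resamples)` tests equality of means between
two small samples (here: 10–15 per-subject means per condition). The
null is imposed by shifting both groups to the pooled mean; resamples
are drawn with replacement within each group; the two-sided p-value is
`(1 + #{|T*| >= |T|}) / (B + 1)`, never exactly zero. The compared
statistic is the *studentized* mean difference (Welch-type plug-in
standard error, recomputed on every resample). We chose studentization
after measuring the calibration of the plain difference-of-means
statistic: at n = 15 per group its type-I error was ≈ 0.07 at α = 0.05
(the plug-in bootstrap variance underestimates the sampling variance by
(n−1)/n, and normal tails understate t tails), while the studentized
version measured ≈ 0.05. The reported `statistic` remains the raw
difference of means; only the comparison is studentized. Each group's
resampling stream is derived from the seed plus the group's own sorted
content, which makes the test exactly symmetric in its arguments.

## The synthetic-data generator

Real recordings of this experiment are not redistributable, so the
package carries a first-class generator (`simulation_config()`,
`simulate_recording()`, `simulate_study()`) that emulates the
experiment and writes the same combined text dialect the reader parses.
Per trial: an onset trigger carrying the condition and operand pair,
`multiplicand` at +2 s, `multiplier` at +4 s; operands uniform on the
condition's range. The pupil trace is

- a per-subject baseline (3.5 ± 0.3 mm between subjects),
- plus `amplitude × kernel(t − onset)`, a log-normal-shaped bump equal
  to 1 at its peak (default 6.5 s, log-width 0.25, so the dilation falls
  in the 6–8 s window), with per-trial amplitude jitter (10% SD),
- plus Gaussian sample noise (0.05 mm SD),
- plus blink gaps (6/min, lengths 2 + Poisson(6) samples, also blanking
  gaze) and isolated spurious outliers (2/min, ±1 mm).

Default conditions: 50 Hz sampling (the nominal rate of the recording
hardware class the dialect mimics — configurable), 10 subjects, 12
trials per condition in randomized order, 10 s epochs with a 2 s
inter-trial interval, and dilation amplitudes 0.05 / 0.15 / 0.30 mm for
easy / medium / difficult. Samples are quantized (pupil 10⁻⁴ mm, gaze
10⁻² px) as a device would, which also makes the text export round-trip
bit-exactly. The generator deliberately omits several features of real
data — pupillary light reflex, hippus, saccade dynamics, slow drifts,
foreshortening — so passing recovery tests demonstrates that the
pipeline is correct and well-calibrated on its stated signal model, not
that it is robust to every artefact of real recordings.

## Reproducibility machinery

- **Determinism.** One top-level seed drives everything; each
  (plugin, subject) execution gets a substream derived from the seed,
  the plugin id and the subject names, so results are independent of
  selection order. Identical inputs and seed give bit-identical derived
  data.
- **Bundles.** `export_bundle()` writes a single uncompressed tar with a
  JSON manifest, raw files byte-exact, all parsed and derived data, the
  workflow with settings, plugin source snapshots and the provenance
  log. Doubles are serialized as `%.17g` text, which round-trips IEEE
  doubles exactly; a re-imported study compares `identical()` to the
  exported one. Imported plugin sources are compiled into a run-local
  registry at execution time, shadowing nothing globally registered.
- **Identifiers.** `compute_uwid()` derives a `ts-XXX-XXX` code (two
  base-36 triplets) from a content hash over the study name, raw-file
  hashes, workflow settings and plugin sources. Identifiers are computed
  locally and deterministically; there is no central registry, so
  determinism substitutes for issued uniqueness.
- **Locking.** After publication a study is locked: every editing
  operation (settings, workflow, subjects) refuses. Running the workflow
  remains permitted on locked studies — it is reproduction, not editing:
  stages recompute deterministically from the attached raw bytes, and
  the provenance log is append-only by design. The lock is archival, not
  cryptographic.
- **Provenance.** Each executed stage appends a record: timestamp,
  plugin id, settings hash, subjects, engine version, input and output
  content hashes. Re-running an identical configuration appends an
  identical record except for the timestamp.

## Numerical and design choices

- Missing values are IEEE `NaN`/`NA` internally; parsers map dialect
  codes to them.
- "Gaps smaller than five samples" is read strictly (`length <
  max_gap`); the boundary is covered by a test.
- Baseline correction is subtractive, the simplest reading; a divisive
  (percent-change) variant would be a one-line change in the extraction
  stage and is intentionally not offered until needed.
- The trial window end is not dictated by the experiment; the default
  epoch `[0, 10)` s comfortably contains the 6–8 s dilation and is
  configurable.
- Latencies are measured from trial start (= event time), earliest
  sample wins ties.
- The engine's error policy defaults to abort; `"continue"` records the
  failing (plugin, subject) pair and leaves that subject's prior-stage
  outputs intact.
- Re-running a stage overwrites its derived outputs for the selected
  subjects; downstream stages are not invalidated automatically (re-run
  them explicitly).
- The plugin contract is three entry points — `declare`, `configure`,
  `process` — a split chosen so that a plugin's self-description, its
  settings validation and its computation are separately testable.

## Problem sizes used by the tests

The test-suite replicates the analysis at the study conditions above
(10 subjects × 12 trials/condition across 40 independent seeds for
recovery; 2000 null replicates at n = 15, B = 500 for the bootstrap's
calibration; B = 5000 for single comparisons) and at reduced sizes
(2 subjects × 3 trials) where only mechanics are exercised. The
acceptance script reruns the full pipeline and reports group condition
means, the easy-vs-difficult bootstrap p-value, recovery rates across
20 seeds, the null rejection rate, and the bundle reproduction checks.

## Known limitations

- One modality level per subject (no nested substructures), uniform
  sampling only.
- No gaze-event parsing (fixations, saccades), no areas-of-interest
  analysis, no pupil foreshortening correction.
- The bootstrap compares two means; no multiple-comparison correction.
- Execution is sequential; the engine does not parallelize across
  subjects.
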