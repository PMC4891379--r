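# Event-related pupillometry workflow for the mental-multiplication task:
# five stages, executed in order.
name: mental-multiplication-pupillometry
stages:
  # 1. parse the combined gaze+event text exports
  - plugin: core/read_file
    settings:
      file_pattern: "*.tsv"
      modality: eyetracking
      timestamp_column: Timestamp
      timestamp_unit: ms
      channel_columns: "GazepointX=gaze_x,GazepointY=gaze_y,Pupil=pupil"
      event_column: Event
      missing_code: -1
  # 2. group the stimulus onset triggers into the three conditions
  - plugin: core/modify_events
    settings:
      rules: "mmult_easy_* -> easy; mmult_medium_* -> medium; mmult_difficult_* -> difficult"
  # 3. fill short tracking-loss gaps (strictly shorter than 5 samples)
  - plugin: core/interpolate_gaps
    settings:
      channels: "*"
      max_gap: 5
      method: linear
  # 4. moving median (outlier removal) then moving mean (smoothing),
  #    both 5 samples in each direction = an 11-sample zero-phase window
  - plugin: core/filter_moving_average
    settings:
      channels: pupil
      halfwidth: 5
      statistic: median+mean
  # 5. extract trials, baseline-correct over [0,2) s, measure the mean
  #    pupil size over [6,7) s per trial, plot condition averages
  - plugin: core/event_related_data_extraction
    settings:
      channel: pupil
      conditions: "easy,medium,difficult"
      trial_start: 0
      trial_end: 10
      baseline_start: 0
      baseline_end: 2
      measure_start: 6
      measure_end: 7
      measures: mean
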