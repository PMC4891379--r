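# The built-in processing stages. Each plugin is the standard triple
# declare/configure/process; registration happens at package load. The
# process() bodies call only exported functions, so the source snapshots
# embedded into studies re-compile anywhere the package is installed.

get_modality <- function(study, si, modality) {
  m <- study$subjects[[si]]$modalities[[modality]]
  if (is.null(m)) {
    pf_error(sprintf("subject '%s' has no modality '%s'",
                     study$subjects[[si]]$name, modality), "pf_plugin_error")
  }
  m
}

#' Split a comma-separated settings value into trimmed elements
#' @param text the settings string.
#' @return character vector.
#' @export
split_csv_setting <- function(text) {
  parts <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

#' Select channels of a modality by a comma-separated name list
#' @param m a [ts_modality()].
#' @param spec channel names, comma-separated, or `"*"` for all.
#' @return character vector of channel names.
#' @export
select_channels <- function(m, spec) {
  if (identical(trimws(spec), "*")) return(names(m$channels))
  sel <- split_csv_setting(spec)
  absent <- setdiff(sel, names(m$channels))
  if (length(absent)) {
    pf_error(sprintf("channel(s) not present: %s",
                     paste(absent, collapse = ", ")), "pf_plugin_error")
  }
  sel
}

# ---- core/read_file ---------------------------------------------------------

declare_read_file <- function() {
  plugin_spec(
    plugin_id = "core/read_file", category = "core",
    title = "Flexible columnar text file reader", scope = "subject",
    settings = list(
      file_pattern = setting_text("*.tsv",
        doc = "glob selecting which attached raw file to parse"),
      modality = setting_text("eyetracking",
        doc = "modality the parsed data are stored under"),
      timestamp_column = setting_text("Timestamp"),
      timestamp_unit = setting_choice("ms", c("ms", "s")),
      channel_columns = setting_text(
        "GazepointX=gaze_x,GazepointY=gaze_y,Pupil=pupil",
        doc = "column=channel pairs, comma-separated"),
      event_column = setting_text("Event",
        doc = "column whose non-empty cells become events; '' for none"),
      missing_code = setting_num(-1,
        doc = "numeric code mapped to missing"),
      sample_rate = setting_num(0, min = 0,
        doc = "declared rate in Hz; 0 infers it from timestamps"),
      rate_tolerance = setting_num(0.01, min = 0, max = 1,
        doc = "max relative deviation of timestamp deltas")
    ),
    doc = "Parses a rows-and-columns text export into channels and events."
  )
}

process_read_file <- function(study, subjects, settings, ctx) {
  si <- subjects
  subj <- study$subjects[[si]]
  files <- names(subj$raw_files)
  hits <- sort(files[grepl(utils::glob2rx(settings$file_pattern), files)])
  if (length(hits) == 0L) {
    pf_error(sprintf("no attached raw file matches pattern '%s'",
                     settings$file_pattern), "pf_plugin_error")
  }
  pairs <- split_csv_setting(settings$channel_columns)
  kv <- strsplit(pairs, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) {
    pf_error("channel_columns must be 'column=channel' pairs",
             "pf_plugin_error")
  }
  channels <- stats::setNames(vapply(kv, `[[`, character(1), 2L),
                              vapply(kv, `[[`, character(1), 1L))
  map <- column_map(
    timestamp_column = settings$timestamp_column,
    timestamp_unit = settings$timestamp_unit,
    channels = channels,
    event_column = if (nzchar(settings$event_column))
      settings$event_column else NULL,
    missing_codes = settings$missing_code,
    sample_rate = if (settings$sample_rate > 0) settings$sample_rate
                  else NULL,
    rate_tolerance = settings$rate_tolerance)
  m <- read_columnar_file(text = rawToChar(subj$raw_files[[hits[1]]]),
                          map = map)
  study$subjects[[si]]$modalities[[settings$modality]] <- m
  study
}

# ---- core/modify_events -----------------------------------------------------

declare_modify_events <- function() {
  plugin_spec(
    plugin_id = "core/modify_events", category = "core",
    title = "Rename events by match rules", scope = "subject",
    settings = list(
      modality = setting_text("eyetracking"),
      rules = setting_text("",
        doc = "ordered 'pattern -> new_name' rules, ';'-separated; '*' and '?' wildcards")
    ),
    doc = "Recodes trigger names, e.g. grouping stimuli into conditions."
  )
}

process_modify_events <- function(study, subjects, settings, ctx) {
  si <- subjects
  m <- get_modality(study, si, settings$modality)
  rules <- parse_event_rules(settings$rules)
  m$events <- modify_events(m$events, rules)
  study$subjects[[si]]$modalities[[settings$modality]] <- m
  study
}

# ---- core/interpolate_gaps --------------------------------------------------

declare_interpolate_gaps <- function() {
  plugin_spec(
    plugin_id = "core/interpolate_gaps", category = "core",
    title = "Interpolate short missing-data gaps", scope = "subject",
    settings = list(
      modality = setting_text("eyetracking"),
      channels = setting_text("*", doc = "channels to fill; '*' for all"),
      max_gap = setting_int(5, min = 1,
        doc = "fill gaps strictly shorter than this many samples"),
      method = setting_choice("linear", c("nearest", "linear", "cubic")),
      max_jump = setting_num(Inf, min = 0,
        doc = "skip gaps whose flanks differ by more than this"),
      valid_min = setting_num(-Inf),
      valid_max = setting_num(Inf)
    ),
    doc = "Replaces short NA runs (blinks, tracking loss) by interpolation."
  )
}

process_interpolate_gaps <- function(study, subjects, settings, ctx) {
  si <- subjects
  m <- get_modality(study, si, settings$modality)
  max_jump <- if (is.finite(settings$max_jump)) settings$max_jump else NULL
  valid_range <- if (is.finite(settings$valid_min) ||
                     is.finite(settings$valid_max)) {
    c(settings$valid_min, settings$valid_max)
  } else NULL
  for (chn in select_channels(m, settings$channels)) {
    m$channels[[chn]] <- interpolate_gaps(m$channels[[chn]],
                                          max_gap = settings$max_gap,
                                          method = settings$method,
                                          max_jump = max_jump,
                                          valid_range = valid_range)
  }
  study$subjects[[si]]$modalities[[settings$modality]] <- m
  study
}

# ---- core/filter_moving_average ---------------------------------------------

declare_filter_moving <- function() {
  plugin_spec(
    plugin_id = "core/filter_moving_average", category = "core",
    title = "Zero-phase sliding-window mean/median filter",
    scope = "subject",
    settings = list(
      modality = setting_text("eyetracking"),
      channels = setting_text("pupil"),
      halfwidth = setting_int(5, min = 0,
        doc = "window extends this many samples in both directions"),
      statistic = setting_choice("mean", c("mean", "median",
                                           "median+mean"),
        doc = "'median+mean' runs a median pass then a mean pass, same window")
    ),
    doc = "Outlier-robust smoothing with a symmetric (phase-free) window."
  )
}

process_filter_moving <- function(study, subjects, settings, ctx) {
  si <- subjects
  m <- get_modality(study, si, settings$modality)
  stats_seq <- if (settings$statistic == "median+mean") {
    c("median", "mean")
  } else {
    settings$statistic
  }
  for (chn in select_channels(m, settings$channels)) {
    for (st in stats_seq) {
      m$channels[[chn]] <- moving_filter(m$channels[[chn]],
                                         halfwidth = settings$halfwidth,
                                         statistic = st)
    }
  }
  study$subjects[[si]]$modalities[[settings$modality]] <- m
  study
}

# ---- core/event_related_data_extraction -------------------------------------

declare_event_related <- function() {
  plugin_spec(
    plugin_id = "core/event_related_data_extraction", category = "core",
    title = "Extract event-related trials, measures and averages",
    scope = "group",
    settings = list(
      modality = setting_text("eyetracking"),
      channel = setting_text("pupil"),
      conditions = setting_text("easy,medium,difficult"),
      trial_start = setting_num(0), trial_end = setting_num(10),
      baseline_start = setting_num(0), baseline_end = setting_num(2),
      measure_start = setting_num(6), measure_end = setting_num(7),
      measures = setting_text("mean",
        doc = "comma-separated: mean, median, min, max, latency_to_min, latency_to_max, range"),
      confidence = setting_num(0.95, min = 0.5, max = 0.999),
      derived_name = setting_text("eventrelateddata"),
      write_outputs = setting_flag(TRUE,
        doc = "write the trial table and the averages figure to the run directory")
    ),
    doc = "Per-condition baseline-corrected trials, scalar trial measures, and group average curves with confidence bands."
  )
}

process_event_related <- function(study, subjects, settings, ctx) {
  conditions <- split_csv_setting(settings$conditions)
  measures <- split_csv_setting(settings$measures)
  tables <- list()
  all_trials <- list()
  times <- NULL
  for (si in subjects) {
    subj <- study$subjects[[si]]
    m <- get_modality(study, si, settings$modality)
    ch <- m$channels[[settings$channel]]
    if (is.null(ch)) {
      pf_error(sprintf("subject '%s' has no channel '%s'", subj$name,
                       settings$channel), "pf_plugin_error")
    }
    res <- extract_event_related(
      ch, m$events, conditions,
      trial_window = c(settings$trial_start, settings$trial_end),
      baseline_window = c(settings$baseline_start, settings$baseline_end),
      measure_window = c(settings$measure_start, settings$measure_end),
      measures = measures, conf_level = settings$confidence)
    times <- res$data$times
    m$derived[[settings$derived_name]] <- res$data
    study$subjects[[si]]$modalities[[settings$modality]] <- m
    if (nrow(res$measures)) {
      tables[[subj$name]] <- cbind(subject = subj$name, res$measures)
    }
    for (cn in conditions) {
      all_trials[[cn]] <- rbind(all_trials[[cn]],
                                res$data$conditions[[cn]]$trials)
    }
  }
  table <- if (length(tables)) {
    do.call(rbind, c(tables, list(make.row.names = FALSE)))
  } else {
    data.frame(subject = character(), condition = character(),
               trial = integer(), measure = character(), value = numeric())
  }
  curves <- pooled_condition_curves(all_trials, times = times,
                                    conf_level = settings$confidence)
  fig <- plot_condition_averages(curves, channel = settings$channel)
  if (isTRUE(settings$write_outputs) && !is.null(ctx$output_dir)) {
    data.table::fwrite(table, file.path(ctx$output_dir,
                                        "trial_measures.tsv"),
                       sep = "\t", quote = FALSE)
    save_figure(fig, file.path(ctx$output_dir, "condition_averages.pdf"))
  }
  list(study = study, outputs = list(table = table, curves = curves,
                                     figure = fig))
}

#' Pointwise condition averages with confidence bands over pooled trials
#' @param trials named list (condition -> trials x samples matrix).
#' @param times sample times from trial start; inferred if `NULL`.
#' @param conf_level confidence level of the pointwise normal band.
#' @param sample_rate rate used to infer `times` when needed.
#' @return data frame `(condition, time, mean, lo, hi, n)`.
#' @export
pooled_condition_curves <- function(trials, times = NULL,
                                    conf_level = 0.95, sample_rate = NULL) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  do.call(rbind, lapply(names(trials), function(cn) {
    tr <- trials[[cn]]
    if (is.null(tr) || nrow(tr) == 0L) return(NULL)
    tm <- times %||% (seq_len(ncol(tr)) - 1) / (sample_rate %||% 1)
    m <- colMeans(tr, na.rm = TRUE)
    nn <- colSums(!is.na(tr))
    s <- apply(tr, 2, stats::sd, na.rm = TRUE)
    se <- ifelse(nn > 1, s / sqrt(nn), NA_real_)
    data.frame(condition = cn, time = tm, mean = m, lo = m - z * se,
               hi = m + z * se, n = nn, stringsAsFactors = FALSE,
               row.names = NULL)
  }))
}

# ---- test/bootstrap (custom example plugin) ---------------------------------

declare_test_bootstrap <- function() {
  plugin_spec(
    plugin_id = "test/bootstrap", category = "custom/test",
    title = "Group line plot + bootstrap comparison of two conditions",
    scope = "group",
    settings = list(
      modality = setting_text("eyetracking"),
      derived_name = setting_text("eventrelateddata"),
      conditions = setting_text("easy,medium,difficult"),
      condition_a = setting_text("easy"),
      condition_b = setting_text("difficult"),
      n_resamples = setting_int(5000, min = 1),
      write_outputs = setting_flag(TRUE)
    ),
    doc = "Per-subject condition means, plotted per subject, with a two-sample bootstrap p-value between two conditions in the title."
  )
}

process_test_bootstrap <- function(study, subjects, settings, ctx) {
  if (length(subjects) == 0L) {
    return(list(study = study, outputs = NULL))
  }
  conditions <- split_csv_setting(settings$conditions)
  mat <- summarize_per_subject(study, conditions, subjects = subjects,
                               modality = settings$modality,
                               derived_name = settings$derived_name)
  for (cn in c(settings$condition_a, settings$condition_b)) {
    if (!cn %in% rownames(mat)) {
      pf_error(sprintf("condition '%s' not among summarized conditions",
                       cn), "pf_plugin_error")
    }
  }
  res <- bootstrap_pvalue(mat[settings$condition_a, ],
                          mat[settings$condition_b, ],
                          n_resamples = settings$n_resamples,
                          seed = ctx$seed)
  fig <- plot_condition_means(mat, p_value = res$p_value,
                              condition_a = settings$condition_a,
                              condition_b = settings$condition_b)
  if (isTRUE(settings$write_outputs) && !is.null(ctx$output_dir)) {
    save_figure(fig, file.path(ctx$output_dir, "condition_means.pdf"))
  }
  list(study = study,
       outputs = list(condition_means = mat, bootstrap = res,
                      figure = fig))
}

register_builtin_plugins <- function() {
  reg <- function(declare, process) {
    if (is.null(.registry[[declare()$plugin_id]])) {
      register_plugin(declare = declare, configure = configure_by_schema,
                      process = process)
    }
  }
  reg(declare_read_file, process_read_file)
  reg(declare_modify_events, process_modify_events)
  reg(declare_interpolate_gaps, process_interpolate_gaps)
  reg(declare_filter_moving, process_filter_moving)
  reg(declare_event_related, process_event_related)
  reg(declare_test_bootstrap, process_test_bootstrap)
}
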