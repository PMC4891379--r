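#' Uniformly sampled time-series channel
#'
#' The basic signal container every filter and interpolator acts on. Samples
#' are implied uniform: the time of sample `i` (0-based) is
#' `start_time + i / sample_rate`. Missing samples (blink gaps, tracking
#' loss) are `NA`; parsers map format-specific missing codes to `NA` so no
#' sentinel magnitudes survive into analysis.
#'
#' @param name channel name, e.g. `"pupil"`.
#' @param values numeric vector of samples; `NA` marks missing.
#' @param sample_rate sampling rate in Hz (positive).
#' @param start_time time of the first sample in seconds.
#' @param units unit label, e.g. `"mm"`.
#' @return an object of class `ts_channel`.
#' @examples
#' ch <- ts_channel("pupil", c(3.1, NA, 3.3), sample_rate = 50)
#' channel_times(ch)
#' @export
ts_channel <- function(name, values, sample_rate, start_time = 0,
                       units = "") {
  stopifnot(is_string(name), is.numeric(values),
            is_num1(sample_rate), sample_rate > 0,
            is_num1(start_time), is_string(units))
  structure(list(name = name, values = as.numeric(values),
                 sample_rate = as.numeric(sample_rate),
                 start_time = as.numeric(start_time), units = units),
            class = "ts_channel")
}

#' Sample times of a channel
#' @param ch a [ts_channel()].
#' @return numeric vector of times in seconds, one per sample.
#' @export
channel_times <- function(ch) {
  ch$start_time + (seq_along(ch$values) - 1) / ch$sample_rate
}

#' End of a channel's recording (time of the last sample), seconds
#' @param ch a [ts_channel()].
#' @export
channel_end_time <- function(ch) {
  n <- length(ch$values)
  if (n == 0L) return(ch$start_time)
  ch$start_time + (n - 1) / ch$sample_rate
}

#' @export
print.ts_channel <- function(x, ...) {
  cat(sprintf("<ts_channel '%s'> %d samples @ %g Hz, start %g s%s, %d missing\n",
              x$name, length(x$values), x$sample_rate, x$start_time,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              sum(is.na(x$values))))
  invisible(x)
}

#' Condition-labelled time markers
#'
#' An event list is kept sorted ascending by time; ties preserve insertion
#' order (stable sort), so simultaneous triggers keep their recorded order.
#'
#' @param name character vector of event labels.
#' @param time numeric vector of event times, seconds from the channel time
#'   origin.
#' @return a data frame of class `event_list` with columns `name`, `time`.
#' @export
event_list <- function(name = character(), time = numeric()) {
  stopifnot(is.character(name), is.numeric(time),
            length(name) == length(time))
  ord <- order(time)  # order() is stable: ties keep insertion order
  structure(data.frame(name = as.character(name)[ord],
                       time = as.numeric(time)[ord],
                       stringsAsFactors = FALSE),
            class = c("event_list", "data.frame"))
}

is_sorted_events <- function(ev) {
  nrow(ev) < 2L || !is.unsorted(ev$time)
}

#' Modality: a named group of channels plus its events
#'
#' One recording methodology of one subject (e.g. `"eyetracking"`). All
#' channels within a modality share one sampling rate and time origin, so
#' events index into every channel identically. `derived` holds results
#' written by processing stages (e.g. event-related data).
#'
#' @param channels named list of [ts_channel()] objects.
#' @param events an [event_list()].
#' @param derived named list of stage outputs.
#' @return an object of class `ts_modality`.
#' @export
ts_modality <- function(channels = list(), events = event_list(),
                        derived = list()) {
  stopifnot(is.list(channels), inherits(events, "event_list"),
            is.list(derived))
  if (length(channels) && is.null(names(channels))) {
    names(channels) <- vapply(channels, `[[`, character(1), "name")
  }
  structure(list(channels = channels, events = events, derived = derived),
            class = "ts_modality")
}

#' Subject: a named unit of recorded data
#'
#' Holds zero or more modality substructures and the attached raw files
#' (byte-exact, so original exports can always be extracted from a bundle).
#'
#' @param name subject name.
#' @param modalities named list of [ts_modality()] objects.
#' @param raw_files named list of raw vectors (file name -> bytes).
#' @return an object of class `ts_subject`.
#' @export
ts_subject <- function(name, modalities = list(), raw_files = list()) {
  stopifnot(is_string(name), is.list(modalities), is.list(raw_files))
  structure(list(name = name, modalities = modalities,
                 raw_files = raw_files),
            class = "ts_subject")
}

#' Attach a raw file to a subject
#' @param subject a [ts_subject()].
#' @param path file on disk, read byte-exact.
#' @param name stored file name; defaults to `basename(path)`.
#' @return the modified subject.
#' @export
attach_raw_file <- function(subject, path, name = basename(path)) {
  stopifnot(inherits(subject, "ts_subject"), file.exists(path))
  subject$raw_files[[name]] <- readBin(path, "raw", file.size(path))
  subject
}

#' Study: the root container of an analysis
#'
#' A study bundles everything needed to reproduce an analysis: the subjects
#' (with their raw files), the ordered workflow of configured plugin
#' instances, source snapshots of every plugin used, a provenance log, and
#' the archival state (content-derived identifier plus lock flag). Workflow
#' order is significant: stages are always executed in list order.
#'
#' @param name study name.
#' @param subjects list of [ts_subject()] objects.
#' @param workflow ordered list of plugin instances (see [instantiate()]).
#' @return an object of class `ts_study`.
#' @seealso [validate_study()], [run_workflow()], [export_bundle()],
#'   [lock_study()]
#' @export
ts_study <- function(name, subjects = list(), workflow = list()) {
  stopifnot(is_string(name), is.list(subjects), is.list(workflow))
  structure(list(name = name, uwid = NULL, locked = FALSE,
                 engine_version = engine_version(),
                 subjects = subjects, workflow = workflow,
                 plugin_sources = list(), provenance = list()),
            class = "ts_study")
}

#' Version string of the workflow engine
#'
#' Recorded in every provenance record and bundle manifest, so an archived
#' analysis states which engine ran it.
#' @export
engine_version <- function() {
  as.character(utils::packageVersion("pupilflow"))
}

subject_names <- function(study) {
  vapply(study$subjects, `[[`, character(1), "name")
}

assert_unlocked <- function(study, what = "modify") {
  if (isTRUE(study$locked)) {
    pf_error(sprintf("study '%s' is locked; refusing to %s it",
                     study$name, what), "pf_locked_error")
  }
  invisible(study)
}

#' Add a subject to a study
#' @param study a [ts_study()]; must be unlocked.
#' @param subject a [ts_subject()].
#' @return the modified study.
#' @export
add_subject <- function(study, subject) {
  assert_unlocked(study, "add a subject to")
  stopifnot(inherits(subject, "ts_subject"))
  if (subject$name %in% subject_names(study)) {
    pf_error(sprintf("duplicate subject name '%s'", subject$name),
             "pf_model_error")
  }
  study$subjects[[length(study$subjects) + 1L]] <- subject
  study
}

#' Append a configured plugin instance to the workflow
#' @param study a [ts_study()]; must be unlocked.
#' @param instance a plugin instance from [instantiate()].
#' @return the modified study.
#' @export
workflow_append <- function(study, instance) {
  assert_unlocked(study, "extend the workflow of")
  stopifnot(inherits(instance, "plugin_instance"))
  study$workflow[[length(study$workflow) + 1L]] <- instance
  study
}

#' Change the settings of one workflow stage
#'
#' Re-instantiates the stage with the given overrides, validated against the
#' plugin's schema. Rejected on locked studies.
#'
#' @param study a [ts_study()].
#' @param stage 1-based index into the workflow.
#' @param overrides named list of settings values.
#' @return the modified study.
#' @export
update_stage_settings <- function(study, stage, overrides) {
  assert_unlocked(study, "change settings of")
  stopifnot(is_count(stage), stage <= length(study$workflow))
  inst <- study$workflow[[stage]]
  merged <- utils::modifyList(inst$settings, overrides)
  study$workflow[[stage]] <- instantiate(inst$plugin_id, "default", merged)
  study
}

#' Validate a study against the model invariants
#'
#' Checks well-formedness only; the lock flag is orthogonal (a locked study
#' can be perfectly valid). Violations are returned as messages naming the
#' offending subject/modality, never raised.
#'
#' @param study a [ts_study()].
#' @return character vector of violation descriptions; empty if valid.
#' @export
validate_study <- function(study) {
  v <- character()
  say <- function(...) v <<- c(v, sprintf(...))
  if (!inherits(study, "ts_study")) {
    return("not a ts_study object")
  }
  if (!is_string(study$name) || !nzchar(study$name)) say("study name is empty")
  nms <- subject_names(study)
  if (anyDuplicated(nms)) {
    say("duplicate subject names: %s",
        paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  for (s in study$subjects) {
    if (!inherits(s, "ts_subject")) { say("subject entry is not a ts_subject"); next }
    for (mn in names(s$modalities)) {
      m <- s$modalities[[mn]]
      where <- sprintf("subject '%s', modality '%s'", s$name, mn)
      if (!inherits(m, "ts_modality")) { say("%s: not a ts_modality", where); next }
      rates <- vapply(m$channels, `[[`, numeric(1), "sample_rate")
      starts <- vapply(m$channels, `[[`, numeric(1), "start_time")
      if (length(rates) > 1L && (length(unique(rates)) > 1L ||
                                 length(unique(starts)) > 1L)) {
        say("%s: channels disagree on sample rate or time origin", where)
      }
      for (ch in m$channels) {
        if (ch$sample_rate <= 0) say("%s: channel '%s' has nonpositive rate",
                                     where, ch$name)
      }
      if (!inherits(m$events, "event_list")) {
        say("%s: events are not an event_list", where)
      } else {
        if (!is_sorted_events(m$events)) {
          say("%s: event list is not sorted by time", where)
        }
        if (length(m$channels) && nrow(m$events)) {
          t0 <- min(starts)
          t1 <- max(vapply(m$channels, channel_end_time, numeric(1)))
          bad <- m$events$time < t0 | m$events$time > t1
          if (any(bad)) {
            say("%s: %d event(s) outside the recording [%g, %g] s",
                where, sum(bad), t0, t1)
          }
        }
      }
    }
    for (fn in names(s$raw_files)) {
      if (!is.raw(s$raw_files[[fn]])) {
        say("subject '%s': raw file '%s' is not raw bytes", s$name, fn)
      }
    }
  }
  for (i in seq_along(study$workflow)) {
    inst <- study$workflow[[i]]
    if (!inherits(inst, "plugin_instance")) {
      say("workflow stage %d is not a plugin_instance", i)
      next
    }
    if ((isTRUE(study$locked) || !is.null(study$uwid) ||
         length(study$provenance)) &&
        is.null(study$plugin_sources[[inst$source_ref]])) {
      say("workflow stage %d ('%s') has no source snapshot", i,
          inst$plugin_id)
    }
  }
  v
}

#' @export
print.ts_study <- function(x, ...) {
  cat(sprintf("<ts_study '%s'>%s%s\n", x$name,
              if (!is.null(x$uwid)) paste0(" uwid=", x$uwid) else "",
              if (isTRUE(x$locked)) " [locked]" else ""))
  cat(sprintf("  engine %s; %d subject(s); %d workflow stage(s); %d provenance record(s)\n",
              x$engine_version, length(x$subjects), length(x$workflow),
              length(x$provenance)))
  for (s in x$subjects) {
    cat(sprintf("  - %s: %s; files: %s\n", s$name,
                if (length(s$modalities))
                  paste(names(s$modalities), collapse = ", ") else "(no data)",
                if (length(s$raw_files))
                  paste(names(s$raw_files), collapse = ", ") else "none"))
  }
  for (i in seq_along(x$workflow)) {
    inst <- x$workflow[[i]]
    cat(sprintf("  [%d] %s (settings '%s')\n", i, inst$plugin_id,
                inst$settings_name))
  }
  invisible(x)
}

# Content fingerprint of all measured/derived data of selected subjects;
# used for provenance records and reproduction checks. Binary
# serialization (not the textual canonical form) keeps this cheap enough
# to run before and after every stage.
data_fingerprint <- function(study, subjects = seq_along(study$subjects)) {
  hash_raw(serialize(lapply(study$subjects[subjects], function(s) {
    list(name = s$name, modalities = lapply(s$modalities, unclass_deep))
  }), NULL, version = 2))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  } else {
    x <- unclass(x)
    attributes(x) <- attributes(x)[intersect(names(attributes(x)),
                                             c("names", "dim"))]
  }
  x
}
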