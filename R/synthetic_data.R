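#' Configuration of the synthetic mental-multiplication experiment
#'
#' The generator emulates event-related pupillometry recordings of a
#' mental-multiplication task: each trial starts with a blank screen, the
#' multiplicand appears 2 s after trial onset and the multiplier after
#' 4 s; operand pairs are drawn uniformly from 1-9 (easy), 6-14 (medium)
#' or 11-19 (difficult). The pupil trace is a per-subject baseline plus a
#' task-evoked dilation — a smooth log-normal-shaped bump peaking between
#' 6 and 8 s after onset whose amplitude scales with difficulty — plus
#' Gaussian sample noise, blink gaps (runs of missing samples) and
#' isolated spurious outlier samples. Gaze wanders near the screen centre.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_condition trials per condition per subject.
#' @param sample_rate recording rate, Hz.
#' @param baseline_pupil mean resting pupil diameter, mm.
#' @param baseline_sd_between between-subject SD of the resting diameter,
#'   mm.
#' @param noise_sd per-sample Gaussian noise SD, mm.
#' @param blink_rate blink gaps per minute.
#' @param blink_gap_mean mean gap length in samples; lengths are drawn as
#'   `2 + Poisson(blink_gap_mean - 2)`.
#' @param outlier_rate spurious isolated outlier samples per minute.
#' @param outlier_magnitude absolute size of an outlier excursion, mm.
#' @param amplitudes named numeric vector `c(easy=, medium=, difficult=)`
#'   of dilation amplitudes, mm.
#' @param amplitude_jitter relative per-trial SD of the amplitude.
#' @param kernel_peak time of peak dilation after trial onset, s.
#' @param kernel_width log-scale width of the dilation bump.
#' @param lead_in blank recording before the first trial, s.
#' @param epoch trial epoch length, s.
#' @param iti inter-trial interval between epoch end and next onset, s.
#' @param gaze_center screen centre `c(x, y)` in pixels.
#' @param gaze_sd stationary SD of the gaze wander, pixels.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 10, trials_per_condition = 12,
                              sample_rate = 50, baseline_pupil = 3.5,
                              baseline_sd_between = 0.3, noise_sd = 0.05,
                              blink_rate = 6, blink_gap_mean = 8,
                              outlier_rate = 2, outlier_magnitude = 1,
                              amplitudes = c(easy = 0.05, medium = 0.15,
                                             difficult = 0.30),
                              amplitude_jitter = 0.1, kernel_peak = 6.5,
                              kernel_width = 0.25, lead_in = 2, epoch = 10,
                              iti = 2, gaze_center = c(512, 384),
                              gaze_sd = 40) {
  stopifnot(is_count(n_subjects), is_count(trials_per_condition),
            is_num1(sample_rate), sample_rate > 0,
            is_num1(noise_sd), noise_sd >= 0,
            is_num1(blink_rate), blink_rate >= 0,
            is_num1(blink_gap_mean), blink_gap_mean >= 2,
            is_num1(outlier_rate), outlier_rate >= 0,
            is.numeric(amplitudes), length(amplitudes) == 3L,
            all(amplitudes >= 0),
            setequal(names(amplitudes), c("easy", "medium", "difficult")),
            is_num1(kernel_peak), kernel_peak > 0,
            is_num1(epoch), epoch > 0, is_num1(iti), iti >= 0)
  structure(as.list(environment()), class = "simulation_config")
}

operand_ranges <- list(easy = 1:9, medium = 6:14, difficult = 11:19)

#' Task-evoked pupil response kernel
#'
#' Smooth unimodal log-normal-shaped bump, 0 for `t <= 0`, peaking with
#' value 1 at `t = peak`. The dilation added to the baseline for a trial is
#' `amplitude * kernel(t - onset)`.
#'
#' @param t time since trial onset, s (vectorized).
#' @param peak peak time, s.
#' @param width log-scale width.
#' @return kernel values in `[0, 1]`.
#' @export
pupil_kernel <- function(t, peak = 6.5, width = 0.25) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- exp(-(log(t[pos] / peak))^2 / (2 * width^2))
  out
}

#' Simulate one subject's recording
#'
#' Generates the continuous eyetracking modality (gaze x/y in pixels,
#' pupil in mm) and the trial schedule for one subject. Per trial the
#' events are: an onset trigger named
#' `mmult_<condition>_<a>x<b>` (carrying the operand pair, as stimulus
#' triggers do), `multiplicand` at onset + 2 s and `multiplier` at
#' onset + 4 s. Trial order is randomized. Pupil and gaze samples are
#' quantized to 4 and 2 decimals respectively, as a recording device
#' would, so text export round-trips exactly.
#'
#' @param cfg a [simulation_config()].
#' @param subject_name name for the subject.
#' @param seed integer seed for this recording (the caller's RNG state is
#'   preserved).
#' @return list with elements `modality` (a [ts_modality()]),
#'   `schedule` (data frame `trial, condition, multiplicand, multiplier,
#'   onset`) and `clean_pupil` (the noiseless, gap-free ground-truth pupil
#'   trace).
#' @export
simulate_recording <- function(cfg, subject_name, seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"), is_string(subject_name))
  with_seed(seed, {
    rate <- cfg$sample_rate
    conds <- rep(names(cfg$amplitudes), each = cfg$trials_per_condition)
    conds <- sample(conds)
    n_trials <- length(conds)
    spacing <- cfg$epoch + cfg$iti
    onsets <- cfg$lead_in + (seq_len(n_trials) - 1) * spacing
    # snap onsets to the sample grid so events round-trip through ms text
    onsets <- round(onsets * rate) / rate
    duration <- cfg$lead_in + n_trials * spacing
    n <- as.integer(round(duration * rate))
    tt <- (seq_len(n) - 1) / rate
    a <- integer(n_trials); b <- integer(n_trials)
    for (k in seq_len(n_trials)) {
      rng <- operand_ranges[[conds[k]]]
      a[k] <- sample(rng, 1L)
      b[k] <- sample(rng, 1L)
    }
    base <- cfg$baseline_pupil + stats::rnorm(1, 0, cfg$baseline_sd_between)
    clean <- rep(base, n)
    for (k in seq_len(n_trials)) {
      amp <- cfg$amplitudes[[conds[k]]] *
        max(0, 1 + stats::rnorm(1, 0, cfg$amplitude_jitter))
      w <- which(tt > onsets[k] & tt < onsets[k] + spacing + 4)
      clean[w] <- clean[w] + amp * pupil_kernel(tt[w] - onsets[k],
                                                cfg$kernel_peak,
                                                cfg$kernel_width)
    }
    pupil <- clean + stats::rnorm(n, 0, cfg$noise_sd)
    # spurious isolated outliers
    n_out <- stats::rpois(1, cfg$outlier_rate * duration / 60)
    if (n_out > 0) {
      at <- sample.int(n, min(n_out, n))
      pupil[at] <- pupil[at] + sample(c(-1, 1), length(at), TRUE) *
        cfg$outlier_magnitude
    }
    # gaze: AR(1) wander around the screen centre
    phi <- 0.98
    innov_sd <- cfg$gaze_sd * sqrt(1 - phi^2)
    gx <- cfg$gaze_center[1] +
      as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                               method = "recursive"))
    gy <- cfg$gaze_center[2] +
      as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                               method = "recursive"))
    # blink gaps: missing runs affecting pupil and gaze alike
    n_blinks <- stats::rpois(1, cfg$blink_rate * duration / 60)
    gap_lengths <- integer(0)
    if (n_blinks > 0) {
      gap_lengths <- 2L + stats::rpois(n_blinks, cfg$blink_gap_mean - 2)
      starts <- sort(sample.int(n, n_blinks))
      for (k in seq_len(n_blinks)) {
        idx <- starts[k]:min(n, starts[k] + gap_lengths[k] - 1L)
        pupil[idx] <- NA_real_
        gx[idx] <- NA_real_
        gy[idx] <- NA_real_
      }
    }
    pupil <- round(pupil, 4)  # device quantization: 0.1 um
    gx <- round(gx, 2)
    gy <- round(gy, 2)
    ev_name <- c(sprintf("mmult_%s_%02dx%02d", conds, a, b),
                 rep("multiplicand", n_trials),
                 rep("multiplier", n_trials))
    ev_time <- c(onsets, onsets + 2, onsets + 4)
    modality <- ts_modality(
      channels = list(
        gaze_x = ts_channel("gaze_x", gx, rate, 0, "px"),
        gaze_y = ts_channel("gaze_y", gy, rate, 0, "px"),
        pupil = ts_channel("pupil", pupil, rate, 0, "mm")
      ),
      events = event_list(ev_name, ev_time)
    )
    list(modality = modality,
         schedule = data.frame(trial = seq_len(n_trials), condition = conds,
                               multiplicand = a, multiplier = b,
                               onset = onsets, stringsAsFactors = FALSE),
         clean_pupil = clean,
         gap_lengths = gap_lengths)
  })
}

#' Write a modality as a combined gaze+event text export
#'
#' Tab-separated file with a header row and one row per sample: integer
#' millisecond timestamp, gaze x/y, pupil, and an event-label cell that is
#' non-empty only on event rows — gaze data and event data in the same
#' file, as "combined" eyetracker exports arrange them. Missing samples
#' are written with the dialect's missing code.
#'
#' @param modality a [ts_modality()] with channels `gaze_x`, `gaze_y`,
#'   `pupil`.
#' @param path output file path.
#' @param missing_code numeric code standing for a missing sample.
#' @return `path`, invisibly.
#' @seealso [clearview_column_map()] for the matching reader configuration.
#' @export
write_clearview_file <- function(modality, path, missing_code = -1) {
  stopifnot(inherits(modality, "ts_modality"))
  need <- c("gaze_x", "gaze_y", "pupil")
  if (!all(need %in% names(modality$channels))) {
    pf_error("modality must have gaze_x, gaze_y and pupil channels",
             "pf_sim_error")
  }
  ch <- modality$channels
  rate <- ch$pupil$sample_rate
  n <- length(ch$pupil$values)
  tms <- as.integer(round((ch$pupil$start_time + (seq_len(n) - 1) / rate)
                          * 1000))
  code <- function(v) ifelse(is.na(v), missing_code, v)
  evcol <- rep("", n)
  ev <- modality$events
  if (nrow(ev)) {
    rows <- as.integer(ceiling((ev$time - ch$pupil$start_time) * rate
                               - 1e-9)) + 1L
    if (any(rows < 1L | rows > n)) {
      pf_error("event outside the recording cannot be written",
               "pf_sim_error")
    }
    if (anyDuplicated(rows)) {
      pf_error("two events fall on the same sample row; the dialect has one event cell per row",
               "pf_sim_error")
    }
    evcol[rows] <- ev$name
  }
  dt <- data.table::data.table(Timestamp = tms,
                               GazepointX = code(ch$gaze_x$values),
                               GazepointY = code(ch$gaze_y$values),
                               Pupil = code(ch$pupil$values),
                               Event = evcol)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Column map matching [write_clearview_file()]'s dialect
#' @param sample_rate declared rate (Hz); `NULL` infers from timestamps.
#' @param missing_code the dialect's missing-sample code.
#' @return a [column_map()].
#' @export
clearview_column_map <- function(sample_rate = NULL, missing_code = -1) {
  column_map(timestamp_column = "Timestamp", timestamp_unit = "ms",
             channels = c(GazepointX = "gaze_x", GazepointY = "gaze_y",
                          Pupil = "pupil"),
             event_column = "Event", missing_codes = missing_code,
             sample_rate = sample_rate)
}

#' Simulate a whole study
#'
#' Generates `cfg$n_subjects` recordings, writes each as a combined text
#' export, and builds a [ts_study()] whose subjects carry those files as
#' raw bytes — the same starting point as a study assembled from real
#' eyetracker exports. Ground-truth schedules are written alongside as
#' `<subject>_schedule.tsv` for use as test oracles.
#'
#' @param cfg a [simulation_config()].
#' @param dir directory for the generated files (default: a fresh
#'   temporary directory).
#' @param seed integer master seed; each subject gets a derived substream.
#' @param name study name.
#' @return a [ts_study()] with attached raw files and an empty workflow.
#' @export
simulate_study <- function(cfg, dir = tempfile("pfsim"), seed = 1,
                           name = "synthetic-mental-multiplication") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  study <- ts_study(name)
  for (i in seq_len(cfg$n_subjects)) {
    sname <- sprintf("S%02d", i)
    rec <- simulate_recording(cfg, sname,
                              seed = derive_seed(seed, "subject", sname))
    fp <- file.path(dir, paste0(sname, ".tsv"))
    write_clearview_file(rec$modality, fp)
    sched_fp <- file.path(dir, paste0(sname, "_schedule.tsv"))
    data.table::fwrite(rec$schedule, sched_fp, sep = "\t", quote = FALSE)
    subj <- ts_subject(sname)
    subj <- attach_raw_file(subj, fp)
    study <- add_subject(study, subj)
  }
  study
}
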