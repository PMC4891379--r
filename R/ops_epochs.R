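trial_measure_names <- c("mean", "median", "min", "max", "latency_to_min",
                         "latency_to_max", "range")

#' Extract event-related trials with baseline correction and measures
#'
#' Segments a channel into trials time-locked to condition events, applies
#' subtractive baseline correction, and computes scalar measures per trial.
#'
#' Windows are half-open `[start, end)` in seconds relative to the event,
#' so abutting windows (baseline `[0, 2)`, analysis `[6, 7)`) never share a
#' sample. Each event is snapped to the nearest sample at or after its
#' time. A trial whose window would leave the recording is dropped and
#' counted. Baseline correction subtracts the mean of the trial's
#' non-missing baseline samples from the whole trial. Available measures
#' over the measure window: `mean`, `median`, `min`, `max`,
#' `latency_to_min`, `latency_to_max` (seconds from trial start = event
#' time; earliest sample wins ties) and `range` (max - min). A measure over
#' an all-missing window is `NA`.
#'
#' @param ch a [ts_channel()].
#' @param events an [event_list()]; only events whose name is in
#'   `conditions` start trials.
#' @param conditions character vector of condition names.
#' @param trial_window `c(t0, t1)`: trial extent, seconds relative to the
#'   event.
#' @param baseline_window `c(b0, b1)` with `b0 >= t0`: baseline extent.
#' @param measure_window `c(m0, m1)` with `m1 <= t1`: where the scalar
#'   measures are computed.
#' @param measures subset of the available measure names.
#' @param trial_value_measure which measure fills each trial's
#'   `trialvalues` scalar (default `"mean"`).
#' @param conf_level level of the pointwise confidence band on the
#'   per-condition average curve (normal approximation,
#'   mean +/- z * SE across trials).
#' @return a list of class `event_related_result`:
#' \describe{
#'   \item{data}{`event_related_data`: per condition, the baseline-corrected
#'     trials matrix (trials x samples), onset times and `trialvalues`.}
#'   \item{measures}{data frame `(condition, trial, measure, value)` — the
#'     trial measure table.}
#'   \item{curves}{data frame `(condition, time, mean, lo, hi, n)` — the
#'     per-condition average curve with confidence band.}
#'   \item{dropped}{count of trials falling outside the recording.}
#' }
#' @export
extract_event_related <- function(ch, events, conditions,
                                  trial_window = c(0, 10),
                                  baseline_window = c(0, 2),
                                  measure_window = c(6, 7),
                                  measures = "mean",
                                  trial_value_measure = measures[1],
                                  conf_level = 0.95) {
  stopifnot(inherits(ch, "ts_channel"), inherits(events, "event_list"),
            is.character(conditions), length(conditions) >= 1L)
  unknown <- setdiff(c(measures, trial_value_measure), trial_measure_names)
  if (length(unknown)) {
    pf_error(sprintf("unknown measure(s): %s",
                     paste(unknown, collapse = ", ")), "pf_op_error")
  }
  t0 <- trial_window[1]; t1 <- trial_window[2]
  b0 <- baseline_window[1]; b1 <- baseline_window[2]
  m0 <- measure_window[1]; m1 <- measure_window[2]
  if (!(t0 < t1) || !(b0 < b1) || !(m0 < m1)) {
    pf_error("windows must be nonempty: start < end", "pf_op_error")
  }
  if (b0 < t0 || m1 > t1) {
    pf_error("window ordering violated: need baseline start >= trial start and measure end <= trial end",
             "pf_op_error")
  }
  rate <- ch$sample_rate
  eps <- 1e-9
  off <- function(t) as.integer(ceiling(t * rate - eps))
  j_lo <- off(t0); j_hi <- off(t1) - 1L          # [t0, t1)
  b_lo <- off(b0); b_hi <- off(b1) - 1L
  m_lo <- off(m0); m_hi <- off(m1) - 1L
  n_samp <- j_hi - j_lo + 1L
  times <- (j_lo:j_hi) / rate
  n <- length(ch$values)
  hits <- events[events$name %in% conditions, , drop = FALSE]
  if (nrow(hits) == 0L) {
    pf_error(sprintf("no event matches any requested condition (%s)",
                     paste(conditions, collapse = ", ")), "pf_op_error")
  }
  dropped <- 0L
  conds <- stats::setNames(vector("list", length(conditions)), conditions)
  for (cn in conditions) {
    conds[[cn]] <- list(trials = matrix(numeric(0), nrow = 0,
                                        ncol = n_samp),
                        onsets = numeric(), trialvalues = numeric())
  }
  meas_rows <- list()
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  bsel <- (b_lo - j_lo + 1L):(b_hi - j_lo + 1L)
  msel <- (m_lo - j_lo + 1L):(m_hi - j_lo + 1L)
  mtimes <- (m_lo:m_hi) / rate
  for (k in seq_len(nrow(hits))) {
    ev_t <- hits$time[k]
    cn <- hits$name[k]
    i0 <- as.integer(ceiling((ev_t - ch$start_time) * rate - eps))  # 0-based
    lo <- i0 + j_lo; hi <- i0 + j_hi
    if (lo < 0L || hi > n - 1L) {
      dropped <- dropped + 1L
      next
    }
    tr <- ch$values[(lo + 1L):(hi + 1L)]
    bl <- mean(tr[bsel], na.rm = TRUE)
    if (is.nan(bl)) bl <- 0  # all-missing baseline: leave trial uncorrected
    tr <- tr - bl
    conds[[cn]]$trials <- rbind(conds[[cn]]$trials, tr)
    conds[[cn]]$onsets <- c(conds[[cn]]$onsets, ev_t)
    mw <- tr[msel]
    trial_idx <- nrow(conds[[cn]]$trials)
    vals <- compute_measures(mw, mtimes, measures)
    tv <- compute_measures(mw, mtimes, trial_value_measure)[[1]]
    conds[[cn]]$trialvalues <- c(conds[[cn]]$trialvalues, tv)
    meas_rows[[length(meas_rows) + 1L]] <-
      data.frame(condition = cn, trial = trial_idx, measure = measures,
                 value = unlist(vals), stringsAsFactors = FALSE,
                 row.names = NULL)
  }
  for (cn in conditions) dimnames(conds[[cn]]$trials) <- NULL
  curves <- do.call(rbind, lapply(conditions, function(cn) {
    tr <- conds[[cn]]$trials
    if (nrow(tr) == 0L) return(NULL)
    m <- colMeans(tr, na.rm = TRUE)
    nn <- colSums(!is.na(tr))
    s <- apply(tr, 2, stats::sd, na.rm = TRUE)
    se <- ifelse(nn > 1, s / sqrt(nn), NA_real_)
    data.frame(condition = cn, time = times, mean = m,
               lo = m - z * se, hi = m + z * se, n = nn,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  erd <- structure(list(channel = ch$name, sample_rate = rate,
                        trial_window = c(t0, t1),
                        baseline_window = c(b0, b1),
                        measure_window = c(m0, m1), times = times,
                        conditions = conds, dropped = dropped),
                   class = "event_related_data")
  measures_df <- if (length(meas_rows)) {
    do.call(rbind, c(meas_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(condition = character(), trial = integer(),
               measure = character(), value = numeric())
  }
  structure(list(data = erd, measures = measures_df, curves = curves,
                 dropped = dropped),
            class = "event_related_result")
}

# Scalar measures over one trial's measure window. `mw` are the (already
# baseline-corrected) samples; `mtimes` their times from trial start.
compute_measures <- function(mw, mtimes, measures) {
  ok <- !is.na(mw)
  out <- stats::setNames(vector("list", length(measures)), measures)
  for (m in measures) {
    out[[m]] <- if (!any(ok)) NA_real_ else switch(m,
      mean = mean(mw[ok]),
      median = stats::median(mw[ok]),
      min = min(mw[ok]),
      max = max(mw[ok]),
      range = max(mw[ok]) - min(mw[ok]),
      latency_to_min = mtimes[which(mw == min(mw[ok]))[1]],
      latency_to_max = mtimes[which(mw == max(mw[ok]))[1]]
    )
  }
  out
}

#' Per-subject condition means of trial values
#'
#' Builds the conditions x subjects matrix of per-subject mean trial
#' values (missing-ignoring mean) from the event-related data a previous
#' extraction stage stored in each subject's modality. This is the group
#' summary the line plot and the bootstrap comparison consume.
#'
#' @param study a [ts_study()] whose subjects carry event-related data.
#' @param conditions ordered character vector of condition names (rows).
#' @param subjects indices of subjects to include.
#' @param modality modality name.
#' @param derived_name name under which the extraction stage stored its
#'   result.
#' @return numeric matrix `conditions x subjects`; a subject with no trial
#'   in a condition yields `NA`.
#' @export
summarize_per_subject <- function(study, conditions,
                                  subjects = seq_along(study$subjects),
                                  modality = "eyetracking",
                                  derived_name = "eventrelateddata") {
  stopifnot(inherits(study, "ts_study"), is.character(conditions))
  nms <- subject_names(study)[subjects]
  out <- matrix(NA_real_, nrow = length(conditions),
                ncol = length(subjects),
                dimnames = list(conditions, nms))
  seen <- stats::setNames(logical(length(conditions)), conditions)
  for (j in seq_along(subjects)) {
    s <- study$subjects[[subjects[j]]]
    erd <- s$modalities[[modality]]$derived[[derived_name]]
    if (is.null(erd)) {
      pf_error(sprintf("subject '%s' has no derived '%s' in modality '%s'; run the extraction stage first",
                       s$name, derived_name, modality), "pf_op_error")
    }
    for (i in seq_along(conditions)) {
      cn <- conditions[i]
      cond <- erd$conditions[[cn]]
      if (is.null(cond) || length(cond$trialvalues) == 0L) next
      seen[cn] <- TRUE
      tv <- cond$trialvalues
      if (any(!is.na(tv))) out[i, j] <- mean(tv, na.rm = TRUE)
    }
  }
  absent <- conditions[!seen]
  if (length(absent) == length(conditions)) {
    pf_error(sprintf("requested condition(s) absent for all subjects: %s",
                     paste(absent, collapse = ", ")), "pf_op_error")
  }
  out
}

#' @export
print.event_related_data <- function(x, ...) {
  cat(sprintf("<event_related_data> channel '%s' @ %g Hz, trial [%g, %g) s, baseline [%g, %g) s, measure [%g, %g) s\n",
              x$channel, x$sample_rate, x$trial_window[1], x$trial_window[2],
              x$baseline_window[1], x$baseline_window[2],
              x$measure_window[1], x$measure_window[2]))
  for (cn in names(x$conditions)) {
    cat(sprintf("  %s: %d trial(s)\n", cn, nrow(x$conditions[[cn]]$trials)))
  }
  if (x$dropped) cat(sprintf("  %d trial(s) dropped (outside recording)\n",
                             x$dropped))
  invisible(x)
}
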