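#' Describe the column layout of a columnar eyetracker export
#'
#' A column map links the columns of a tab-separated export (such as the
#' "combined" dialect that carries gaze, pupil and event data in one file)
#' to channels and events: which column holds the timestamp and in what
#' unit, which data columns become which channels, which column carries
#' event labels, and which per-column codes mean "missing".
#'
#' @param timestamp_column name of the timestamp column.
#' @param timestamp_unit `"ms"` or `"s"`.
#' @param channels named character vector: `c(column_name = channel_name)`.
#' @param event_column optional column whose non-empty cells become events
#'   named by the cell value at that row's time.
#' @param missing_codes numeric codes (per column or shared) mapped to
#'   missing; empty cells are always missing. E.g. `-1` for gaze/pupil.
#' @param sample_rate declared rate in Hz, or `NULL` to infer it from the
#'   timestamp deltas.
#' @param rate_tolerance maximum relative deviation of any timestamp delta
#'   from the nominal sampling interval.
#' @return an object of class `column_map`.
#' @export
column_map <- function(timestamp_column, timestamp_unit = c("ms", "s"),
                       channels, event_column = NULL, missing_codes = NULL,
                       sample_rate = NULL, rate_tolerance = 0.01) {
  timestamp_unit <- match.arg(timestamp_unit)
  stopifnot(is_string(timestamp_column), is.character(channels),
            length(channels) >= 1L, !is.null(names(channels)))
  if (timestamp_column %in% names(channels)) {
    pf_error("timestamp column cannot also be a data column",
             "pf_reader_error")
  }
  structure(list(timestamp_column = timestamp_column,
                 timestamp_unit = timestamp_unit, channels = channels,
                 event_column = event_column,
                 missing_codes = missing_codes, sample_rate = sample_rate,
                 rate_tolerance = rate_tolerance),
            class = "column_map")
}

#' Read a columnar text export into a modality
#'
#' Flexible reader for row/column text files with a header row: one channel
#' per mapped data column (uniform rate validated against the timestamp
#' deltas), and one event per row whose event cell is non-empty, named by
#' the cell value at that row's time. Missing codes are mapped to `NA` at
#' parse time, so no sentinel magnitudes reach the analysis.
#'
#' @param text file content as a single string or character vector of
#'   lines; alternatively give `file`.
#' @param map a [column_map()].
#' @param file path to the file to read.
#' @return a [ts_modality()] with channels and events.
#' @export
read_columnar_file <- function(text = NULL, map, file = NULL) {
  stopifnot(inherits(map, "column_map"))
  if (is.null(text)) {
    stopifnot(!is.null(file))
    dt <- data.table::fread(file = file, sep = "\t", header = TRUE,
                            colClasses = list(character = map$event_column),
                            na.strings = NULL, data.table = TRUE)
  } else {
    if (length(text) > 1L) text <- paste(text, collapse = "\n")
    dt <- data.table::fread(text = text, sep = "\t", header = TRUE,
                            colClasses = list(character = map$event_column),
                            na.strings = NULL, data.table = TRUE)
  }
  need <- c(map$timestamp_column, names(map$channels), map$event_column)
  absent <- setdiff(need, names(dt))
  if (length(absent)) {
    pf_error(sprintf("mapped column(s) absent from file: %s",
                     paste(absent, collapse = ", ")), "pf_reader_error")
  }
  ts_raw <- dt[[map$timestamp_column]]
  ts_num <- suppressWarnings(as.numeric(ts_raw))
  if (anyNA(ts_num) && length(ts_num)) {
    pf_error(sprintf("unparseable timestamp(s), e.g. row %d",
                     which(is.na(ts_num))[1]), "pf_reader_error")
  }
  tsec <- if (map$timestamp_unit == "ms") ts_num / 1000 else ts_num
  n <- length(tsec)
  if (n >= 2L) {
    d <- diff(tsec)
    nominal <- if (!is.null(map$sample_rate)) 1 / map$sample_rate
               else stats::median(d)
    if (nominal <= 0 || any(abs(d - nominal) > map$rate_tolerance * nominal)) {
      pf_error("timestamps are not uniformly sampled within tolerance",
               "pf_reader_error")
    }
    rate <- 1 / nominal
  } else {
    rate <- map$sample_rate %||% 1
  }
  if (!is.null(map$sample_rate)) rate <- map$sample_rate
  start <- if (n) tsec[1] else 0
  channels <- list()
  for (col in names(map$channels)) {
    vals <- suppressWarnings(as.numeric(dt[[col]]))
    if (!is.null(map$missing_codes)) {
      vals[vals %in% map$missing_codes] <- NA_real_
    }
    chname <- map$channels[[col]]
    channels[[chname]] <- ts_channel(chname, vals, rate, start)
  }
  events <- event_list()
  if (!is.null(map$event_column) && n) {
    labels <- as.character(dt[[map$event_column]])
    labels[is.na(labels)] <- ""
    hit <- nzchar(trimws(labels))
    if (any(hit)) {
      events <- event_list(trimws(labels[hit]), tsec[hit])
    }
  }
  ts_modality(channels = channels, events = events)
}
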