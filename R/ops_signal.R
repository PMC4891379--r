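#' Interpolate short gaps of missing samples
#'
#' Blink and tracking-loss gaps in eyetracker signals are runs of `NA`. A
#' gap (maximal run of missing samples) is filled iff all of the following
#' hold: its length is strictly smaller than `max_gap`; it has valid
#' samples on both sides (edge gaps are never filled); if `max_jump` is
#' set, the absolute difference between the two flanking values does not
#' exceed it (a large jump suggests the eye moved during the gap); if
#' `valid_range` is set, every inserted value lies within it. Originally
#' valid samples are never modified.
#'
#' @param ch a [ts_channel()].
#' @param max_gap fill gaps strictly shorter than this many samples
#'   (a gap of exactly `max_gap` samples is left untouched).
#' @param method `"nearest"`, `"linear"` or `"cubic"` (natural spline
#'   through the valid samples).
#' @param max_jump optional maximum |right flank - left flank| for a gap to
#'   be eligible.
#' @param valid_range optional `c(lo, hi)`; a gap whose interpolant leaves
#'   this range is left unfilled.
#' @return the channel with eligible gaps filled.
#' @examples
#' ch <- ts_channel("pupil", c(1, NA, 3), 50)
#' interpolate_gaps(ch, max_gap = 5, method = "linear")$values  # 1 2 3
#' @export
interpolate_gaps <- function(ch, max_gap, method = c("linear", "nearest",
                                                     "cubic"),
                             max_jump = NULL, valid_range = NULL) {
  stopifnot(inherits(ch, "ts_channel"))
  method <- match.arg(method)
  if (!is_count(max_gap, min = 1)) {
    pf_error("max_gap must be a positive integer", "pf_op_error")
  }
  if (!is.null(max_jump) && !is_num1(max_jump)) {
    pf_error("max_jump must be a single number", "pf_op_error")
  }
  if (!is.null(valid_range)) {
    if (!(is.numeric(valid_range) && length(valid_range) == 2L) ||
        valid_range[1] > valid_range[2]) {
      pf_error("valid_range must be c(lo, hi) with lo <= hi", "pf_op_error")
    }
  }
  v <- ch$values
  n <- length(v)
  if (!anyNA(v) || n == 0L) return(ch)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  valid_idx <- which(!is.na(v))
  for (g in which(r$values)) {
    s <- starts[g]; e <- ends[g]; len <- e - s + 1L
    if (s == 1L || e == n) next           # edge gap
    if (len >= max_gap) next              # strict: len < max_gap only
    left <- v[s - 1L]; right <- v[e + 1L]
    if (!is.null(max_jump) && abs(right - left) > max_jump) next
    fill <- switch(method,
      nearest = {
        k <- seq_len(len)
        ifelse(k - 0 <= (len + 1) / 2, left, right)  # tie -> left flank
      },
      linear = left + (right - left) * seq_len(len) / (len + 1),
      cubic = stats::spline(x = valid_idx, y = v[valid_idx], xout = s:e,
                            method = "natural")$y
    )
    if (!is.null(valid_range) &&
        any(fill < valid_range[1] | fill > valid_range[2])) next
    v[s:e] <- fill
  }
  ch$values <- v
  ch
}

#' Zero-phase moving mean/median filter
#'
#' Sliding-window filter with a symmetric window of `halfwidth` samples on
#' each side (an `2 * halfwidth + 1`-sample window), so features are not
#' shifted in time. Output sample `i` is the chosen statistic over the
#' non-missing values in the window clipped to the channel (windows shrink
#' at the edges; no padding, no truncation, so trial alignment is
#' preserved). A window containing only missing values yields a missing
#' sample. The median variant removes spurious outlier runs of up to
#' `halfwidth` samples; the mean variant smooths.
#'
#' @param ch a [ts_channel()].
#' @param halfwidth window half-width in samples (`>= 0`).
#' @param statistic `"mean"` or `"median"`.
#' @return the filtered channel.
#' @examples
#' ch <- ts_channel("pupil", c(0, 0, 10, 0, 0), 50)
#' moving_filter(ch, 1, "median")$values  # outlier removed
#' @export
moving_filter <- function(ch, halfwidth, statistic = c("mean", "median")) {
  stopifnot(inherits(ch, "ts_channel"))
  statistic <- match.arg(statistic)
  if (!is_count(halfwidth, min = 0)) {
    pf_error("halfwidth must be a nonnegative integer", "pf_op_error")
  }
  ch$values <- moving_stat_cpp(ch$values, as.integer(halfwidth), statistic)
  ch
}

#' Rename events by ordered match rules
#'
#' Applies an ordered list of `pattern -> new name` rules to an event list;
#' the first rule whose pattern matches an event's name renames it.
#' Patterns are literal names or simple wildcard patterns (`*` matches any
#' substring, `?` one character). Times are untouched, non-matching events
#' pass through, and no event is ever deleted, so the count is preserved.
#' This is how raw stimulus triggers (which typically carry stimulus codes)
#' are recoded into condition labels such as easy/medium/difficult.
#'
#' @param events an [event_list()].
#' @param rules named character vector or named list: names are patterns,
#'   values the replacement names. Order is significant.
#' @return the recoded [event_list()].
#' @examples
#' ev <- event_list(c("A", "B", "C"), c(1, 2, 3))
#' modify_events(ev, c(A = "X", B = "X"))$name  # "X" "X" "C"
#' @export
modify_events <- function(events, rules) {
  stopifnot(inherits(events, "event_list"))
  rules <- unlist(rules)
  if (length(rules) == 0L) return(events)
  if (is.null(names(rules)) || any(!nzchar(names(rules)))) {
    pf_error("rules must be named: c(pattern = new_name, ...)",
             "pf_op_error")
  }
  nm <- events$name
  done <- logical(length(nm))
  for (i in seq_along(rules)) {
    pat <- names(rules)[i]
    rx <- utils::glob2rx(pat)
    hit <- !done & grepl(rx, nm)
    nm[hit] <- rules[[i]]
    done <- done | hit
  }
  events$name <- nm
  events
}

# Parse the plugin-settings text form of rename rules:
#   "pat -> new; pat2 -> new2"
parse_event_rules <- function(text) {
  if (!nzchar(trimws(text))) return(character())
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  out <- character()
  for (p in parts) {
    kv <- strsplit(p, "->", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      pf_error(sprintf("malformed event rule '%s' (want 'pattern -> name')",
                       p), "pf_op_error")
    }
    out[trimws(kv[1])] <- trimws(kv[2])
  }
  out
}
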