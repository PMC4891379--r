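#' Plot per-condition average curves with confidence bands
#'
#' The grand-average task-evoked pupil response per condition, with the
#' pointwise confidence band, over time from trial onset.
#'
#' @param curves data frame `(condition, time, mean, lo, hi, n)` as
#'   produced by the extraction stage or [pooled_condition_curves()].
#' @param channel channel name for the y-axis label.
#' @return a ggplot object.
#' @export
plot_condition_averages <- function(curves, channel = "pupil") {
  if (is.null(curves) || nrow(curves) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  curves$condition <- factor(curves$condition,
                             levels = unique(curves$condition))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$mean,
                                       colour = .data$condition,
                                       fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Time from trial onset (s)",
                  y = sprintf("%s (baseline-corrected)", channel),
                  colour = "condition", fill = "condition",
                  title = "Average response per condition") +
    ggplot2::theme_minimal()
}

#' Plot per-subject condition means as connected lines
#'
#' One line per subject across the ordered conditions, the group summary
#' feeding the bootstrap comparison; the bootstrap p-value between two
#' conditions goes into the title.
#'
#' @param mat conditions x subjects matrix from [summarize_per_subject()].
#' @param p_value optional bootstrap p-value to display.
#' @param condition_a,condition_b the compared conditions (for the title).
#' @return a ggplot object.
#' @export
plot_condition_means <- function(mat, p_value = NULL, condition_a = NULL,
                                 condition_b = NULL) {
  df <- data.frame(
    condition = factor(rep(rownames(mat), ncol(mat)),
                       levels = rownames(mat)),
    subject = rep(colnames(mat), each = nrow(mat)),
    value = as.vector(mat), stringsAsFactors = FALSE)
  ttl <- if (!is.null(p_value)) {
    sprintf("Bootstrapped p-value between %s and %s: %.3f",
            condition_a %||% "first", condition_b %||% "second", p_value)
  } else {
    "Per-subject condition means"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$value,
                                   group = .data$subject)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "Pupil size", title = ttl) +
    ggplot2::theme_minimal()
}

#' Save a figure to a file
#' @param fig a ggplot object.
#' @param path output path (extension picks the device; pdf is
#'   device-independent).
#' @param width,height size in inches.
#' @return `path`, invisibly.
#' @export
save_figure <- function(fig, path, width = 7, height = 4.5) {
  ggplot2::ggsave(path, plot = fig, width = width, height = height)
  invisible(path)
}
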