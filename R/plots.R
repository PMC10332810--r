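#' Heatmap of trial-averaged, sorted population responses
#'
#' @param object a `kc_heatmap` from [trial_average_sorted()].
#' @param ... unused.
#' @return a ggplot: cells (sorted rows) x time, one facet per stimulus.
#' @method autoplot kc_heatmap
#' @export
autoplot.kc_heatmap <- function(object, ...) {
  ggplot2::ggplot(object$traces,
                  ggplot2::aes(x = .data$t_s, y = .data$rank, fill = .data$dff)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~stimulus) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * F / F)) +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("cells (sorted by %s response)", object$sort_stimulus))
}

#' Mean +/- SEM trace per stimulus
#'
#' Averages \eqn{\Delta F/F} across cells and trials within each stimulus
#' and draws the mean with a SEM ribbon (SEM across trials). Traces are
#' boxcar-filtered (0.2 s) for display, per the plotting convention;
#' quantification elsewhere always uses the unfiltered data.
#'
#' @param t a dF/F [trial_tensor()].
#' @param stimuli optional subset of stimulus ids.
#' @param filter_width_s boxcar width for display (default 0.2 s).
#' @return a ggplot.
#' @export
plot_trace_summary <- function(t, stimuli = NULL, filter_width_s = 0.2) {
  check_quantifiable(t)
  tf <- boxcar_filter(t, width_s = filter_width_s)
  keep <- if (is.null(stimuli)) unique(tf$trial_labels) else stimuli
  df <- purrr::map_dfr(keep, function(st) {
    trs <- which(tf$trial_labels == st)
    per_trial <- apply(tf$values[, , trs, drop = FALSE], c(2, 3), mean)
    tibble::tibble(stimulus = st,
                   t_s = frame_times(tf),
                   mean = rowMeans(per_trial),
                   sem = apply(per_trial, 1, sem))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$mean,
                                   color = .data$stimulus, fill = .data$stimulus)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3, color = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F))
}

#' Performance-index time series
#'
#' @param object a `pi_result`.
#' @param frame_rate_hz frames per second for the time axis (optional).
#' @param ... unused.
#' @return a ggplot of PI against frame (or time).
#' @method autoplot pi_result
#' @export
autoplot.pi_result <- function(object, frame_rate_hz = NULL, ...) {
  df <- object$pi_series
  if (!is.null(frame_rate_hz)) {
    df$t_s <- (df$frame - 1) / frame_rate_hz
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$pi)) +
      ggplot2::labs(x = "time (s)", y = "PI")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$pi)) +
      ggplot2::labs(x = "frame", y = "PI")
  }
  p + ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() + ggplot2::ylim(-1, 1)
}

#' Transfer-protocol output distributions
#'
#' Model outputs per stimulus class with the decision threshold marked.
#'
#' @param object an `mbon_emulation`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mbon_emulation
#' @export
autoplot.mbon_emulation <- function(object, ...) {
  ggplot2::ggplot(object$outputs,
                  ggplot2::aes(x = .data$stimulus, y = .data$output)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", color = "red", size = 2) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed",
                        color = "grey40") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "model output", x = NULL, title = object$protocol)
}

#' Upwind-displacement arena series
#'
#' @param upwind result of [upwind_displacement()].
#' @return a ggplot of the arena-mean displacement over time.
#' @export
plot_upwind <- function(upwind) {
  ggplot2::ggplot(upwind$arena_series,
                  ggplot2::aes(x = .data$t_s, y = .data$mean_displacement_mm)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "upwind displacement (mm)")
}
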