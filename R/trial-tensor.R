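#' Trial-aligned fluorescence tensor
#'
#' A `trial_tensor` holds ROI fluorescence as a 3-D array indexed by
#' cell x frame x trial, together with the acquisition frame rate, a flag
#' saying whether the values are raw fluorescence (a.u.) or \eqn{\Delta F/F}
#' (dimensionless), the per-field background fluorescence, and the stimulus
#' label of every trial. All trials share the same frame count and are
#' aligned to trial start.
#'
#' @param values numeric array, cell x frame x trial. A cell x frame matrix
#'   is promoted to a single-trial tensor; a plain vector to a single-cell,
#'   single-trial tensor.
#' @param frame_rate_hz acquisition frame rate in Hz (> 0).
#' @param kind `"raw"` for fluorescence in arbitrary units, `"dff"` for
#'   \eqn{\Delta F/F}.
#' @param trial_labels character vector, one stimulus id per trial.
#' @param background scalar background fluorescence (PMT offset plus
#'   autofluorescence) for the imaging field, in the same units as raw
#'   values. Ignored for `kind = "dff"`.
#'
#' @return an object of class `trial_tensor`.
#' @export
trial_tensor <- function(values, frame_rate_hz, kind = c("raw", "dff"),
                         trial_labels = NULL, background = 0) {
  kind <- match.arg(kind)
  if (is.vector(values)) values <- array(values, dim = c(1L, length(values), 1L))
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L || frame_rate_hz <= 0)
    stop("`frame_rate_hz` must be a single positive number", call. = FALSE)
  n_trials <- dim(values)[3L]
  if (is.null(trial_labels)) trial_labels <- as.character(seq_len(n_trials))
  if (length(trial_labels) != n_trials)
    stop("`trial_labels` must have one entry per trial", call. = FALSE)
  if (!is.numeric(background) || length(background) != 1L || !is.finite(background))
    stop("`background` must be a finite scalar", call. = FALSE)
  structure(
    list(values = values, frame_rate_hz = frame_rate_hz, kind = kind,
         trial_labels = as.character(trial_labels), background = background,
         background_subtracted = FALSE, filtered = FALSE),
    class = "trial_tensor"
  )
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<trial_tensor> %d cells x %d frames x %d trials (%s, %.3g Hz)\n",
              d[1], d[2], d[3], x$kind, x$frame_rate_hz))
  cat("  stimuli:", paste(unique(x$trial_labels), collapse = ", "), "\n")
  if (x$filtered) cat("  boxcar-filtered (plotting only)\n")
  invisible(x)
}

#' @export
dim.trial_tensor <- function(x) dim(x$values)

n_cells <- function(t) dim(t$values)[1L]
n_frames <- function(t) dim(t$values)[2L]
n_trials <- function(t) dim(t$values)[3L]

#' Frame times of a trial tensor
#'
#' Frame `k` (1-based) samples time `(k - 1) / frame_rate_hz` seconds from
#' trial start.
#'
#' @param t a [trial_tensor()].
#' @return numeric vector of frame times in seconds.
#' @export
frame_times <- function(t) (seq_len(n_frames(t)) - 1) / t$frame_rate_hz

#' Map a half-open time window to frame indices
#'
#' The window `[a, b)` in seconds maps to 1-based frames
#' `floor(a * rate) + 1` through `floor(b * rate)`; this half-open rule keeps
#' adjacent windows disjoint and alignment-stable.
#'
#' @param a,b window start and end in seconds (relative to trial start).
#' @param rate frame rate in Hz.
#' @param n_frames total frames; the window is clipped (with a warning) if it
#'   overruns the trial.
#' @return integer vector of frame indices.
#' @export
window_frames <- function(a, b, rate, n_frames = NULL) {
  stopifnot(b > a)
  lo <- floor(a * rate) + 1L
  hi <- floor(b * rate)
  if (!is.null(n_frames)) {
    if (lo > n_frames) stop("window lies entirely outside the trial", call. = FALSE)
    if (hi > n_frames) {
      warning("response window truncated to trial length", call. = FALSE)
      hi <- n_frames
    }
  }
  if (hi < lo) stop("window shorter than one frame", call. = FALSE)
  seq.int(lo, hi)
}

#' Convert a trial tensor to a tidy tibble
#'
#' @param x a [trial_tensor()].
#' @param ... unused.
#' @return a tibble with columns `cell`, `frame`, `t_s`, `trial`,
#'   `stimulus`, `value`.
#' @method as_tibble trial_tensor
#' @export
as_tibble.trial_tensor <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    cell = rep(seq_len(d[1]), times = d[2] * d[3]),
    frame = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    trial = rep(seq_len(d[3]), each = d[1] * d[2]),
    stimulus = rep(x$trial_labels, each = d[1] * d[2]),
    t_s = (rep(rep(seq_len(d[2]), each = d[1]), times = d[3]) - 1) / x$frame_rate_hz,
    value = as.vector(x$values)
  )
}

#' Stimulus schedule for a set of trials
#'
#' The schedule is a tibble with one row per odor epoch: `trial`,
#' `stimulus` (the trial's stimulus id), `epoch` (1-based order within the
#' trial), `odor` (one of `"A"`, `"Aprime"`, `"B"`, `"air"`), `onset_s`,
#' `offset_s`. A transition is a trial whose two odor epochs abut with zero
#' gap. Epochs within a trial must be ordered and non-overlapping.
#'
#' @param trial integer trial index.
#' @param stimulus stimulus id per row.
#' @param epoch epoch index within trial.
#' @param odor odor role per epoch.
#' @param onset_s,offset_s epoch boundaries in seconds from trial start.
#' @return a `stim_schedule` tibble.
#' @export
stim_schedule <- function(trial, stimulus, epoch, odor, onset_s, offset_s) {
  s <- tibble::tibble(trial = as.integer(trial), stimulus = as.character(stimulus),
                      epoch = as.integer(epoch), odor = as.character(odor),
                      onset_s = onset_s, offset_s = offset_s)
  validate_schedule(s)
  class(s) <- c("stim_schedule", class(s))
  s
}

odor_roles <- c("A", "Aprime", "B", "air")

validate_schedule <- function(s) {
  stopifnot(all(c("trial", "stimulus", "epoch", "odor", "onset_s", "offset_s") %in% names(s)))
  if (!all(s$odor %in% odor_roles))
    stop("odor must be one of: ", paste(odor_roles, collapse = ", "), call. = FALSE)
  if (any(s$onset_s >= s$offset_s)) stop("epoch onset must precede offset", call. = FALSE)
  for (tr in unique(s$trial)) {
    e <- s[s$trial == tr, ]
    e <- e[order(e$epoch), ]
    if (nrow(e) > 1 && any(e$onset_s[-1] < e$offset_s[-nrow(e)] - 1e-9))
      stop("epochs overlap in trial ", tr, call. = FALSE)
  }
  invisible(s)
}

#' Identify transition trials in a schedule
#'
#' A transition trial has exactly two non-air odor epochs with zero gap
#' between them.
#'
#' @param schedule a [stim_schedule()].
#' @return tibble with columns `trial`, `stimulus`, `is_transition`.
#' @export
transition_trials <- function(schedule) {
  schedule |>
    dplyr::filter(.data$odor != "air") |>
    dplyr::group_by(.data$trial, .data$stimulus) |>
    dplyr::summarise(
      is_transition = dplyr::n() == 2 &&
        abs(max(.data$onset_s) - min(.data$offset_s)) < 1e-9,
      .groups = "drop"
    )
}

schedule_epoch <- function(schedule, trial, which = c("first", "second", "last")) {
  which <- match.arg(which)
  e <- schedule[schedule$trial == trial & schedule$odor != "air", ]
  e <- e[order(e$onset_s), ]
  if (nrow(e) == 0) stop("trial ", trial, " has no odor epoch", call. = FALSE)
  i <- switch(which, first = 1L, second = 2L, last = nrow(e))
  if (i > nrow(e)) stop("trial ", trial, " has no ", which, " odor epoch", call. = FALSE)
  e[i, ]
}
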