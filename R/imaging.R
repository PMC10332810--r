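#' Subtract field background fluorescence
#'
#' Removes the per-field background (PMT offset plus autofluorescence) from
#' every raw fluorescence value. Must be applied exactly once, before
#' [compute_dff()]; a second application is an error, as is applying it to
#' \eqn{\Delta F/F} data.
#'
#' @param t a raw [trial_tensor()].
#' @param background optional override of the tensor's stored background.
#' @return the tensor with `values - background`, still `kind = "raw"`.
#' @export
subtract_background <- function(t, background = NULL) {
  stopifnot(inherits(t, "trial_tensor"))
  if (t$kind == "dff")
    stop("cannot subtract background from dF/F data", call. = FALSE)
  if (isTRUE(t$background_subtracted))
    stop("background already subtracted from this tensor", call. = FALSE)
  bg <- if (is.null(background)) t$background else background
  if (!is.finite(bg)) stop("background must be finite", call. = FALSE)
  if (bg >= min(t$values))
    warning("background >= minimum fluorescence; negative F possible", call. = FALSE)
  t$values <- t$values - bg
  t$background <- bg
  t$background_subtracted <- TRUE
  t
}

#' Compute \eqn{\Delta F/F}
#'
#' Per cell and per trial, \eqn{\Delta F/F_i = (F_i - F_0) / F_0} where
#' \eqn{F_0} is the mean fluorescence over a baseline window on that same
#' trial, prior to odor delivery. The default baseline is the 8 s
#' immediately preceding `first_onset_s`.
#'
#' @param t a background-subtracted raw [trial_tensor()].
#' @param baseline_window_s length of the baseline window in seconds.
#' @param first_onset_s time of the first odor onset; the baseline window is
#'   `[first_onset_s - baseline_window_s, first_onset_s)`.
#' @return a [trial_tensor()] with `kind = "dff"`.
#' @export
compute_dff <- function(t, baseline_window_s = 8, first_onset_s = baseline_window_s) {
  stopifnot(inherits(t, "trial_tensor"))
  if (t$kind == "dff") stop("tensor is already dF/F", call. = FALSE)
  if (!isTRUE(t$background_subtracted))
    stop("subtract background before computing dF/F", call. = FALSE)
  if (first_onset_s - baseline_window_s < -1e-9)
    stop("baseline window starts before trial start", call. = FALSE)
  idx <- window_frames(first_onset_s - baseline_window_s, first_onset_s,
                       t$frame_rate_hz, n_frames(t))
  f0 <- apply(t$values[, idx, , drop = FALSE], c(1, 3), mean)  # cell x trial
  bad <- which(f0 <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    off <- paste(sprintf("(cell %d, trial %d)", bad[, 1], bad[, 2]), collapse = ", ")
    stop("non-positive baseline F0 for: ", off, call. = FALSE)
  }
  nf <- n_frames(t)
  for (tr in seq_len(n_trials(t)))
    t$values[, , tr] <- (t$values[, , tr] - f0[, tr]) / f0[, tr]
  t$kind <- "dff"
  t$baseline_window <- c(first_onset_s - baseline_window_s, first_onset_s)
  t
}

#' Boxcar filter for plotted traces
#'
#' Centered moving average with the window shrunk at the edges. Filtering is
#' for display only: a filtered tensor is flagged and refused by the
#' quantification functions, which always operate on unfiltered
#' \eqn{\Delta F/F}.
#'
#' @param x a numeric trace or a [trial_tensor()].
#' @param width_s window width in seconds (default 0.2).
#' @param rate frame rate in Hz (taken from the tensor when `x` is one).
#' @return filtered trace or tensor (tensor gains `filtered = TRUE`).
#' @export
boxcar_filter <- function(x, width_s = 0.2, rate = NULL) {
  if (inherits(x, "trial_tensor")) {
    rate <- x$frame_rate_hz
    w <- max(1L, as.integer(round(width_s * rate)))
    x$values <- apply(x$values, c(1, 3), boxcar_vec, w = w) |>
      aperm(c(2, 1, 3))
    x$filtered <- TRUE
    return(x)
  }
  if (is.null(rate)) stop("`rate` required for a plain trace", call. = FALSE)
  w <- max(1L, as.integer(round(width_s * rate)))
  boxcar_vec(x, w)
}

# moving mean over w frames; frame i averages offsets -floor((w-1)/2)..+ceiling((w-1)/2),
# window shrunk at the edges
boxcar_vec <- function(v, w) {
  if (w <= 1L) return(v)
  n <- length(v)
  lo_off <- floor((w - 1) / 2)
  hi_off <- ceiling((w - 1) / 2)
  vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - lo_off):min(n, i + hi_off)])
  }, numeric(1))
}

check_quantifiable <- function(t) {
  if (!inherits(t, "trial_tensor")) stop("expected a trial_tensor", call. = FALSE)
  if (t$kind != "dff") stop("quantification requires dF/F data", call. = FALSE)
  if (isTRUE(t$filtered))
    stop("quantification must use unfiltered dF/F (filtered tensors are for plotting)",
         call. = FALSE)
  invisible(t)
}

#' Response window specification
#'
#' @param start_s offset of the window start from the epoch onset, seconds.
#' @param duration_s window length in seconds (default 8, the standard
#'   averaging window for response amplitudes).
#' @return a `response_window` list.
#' @export
response_window <- function(start_s = 0, duration_s = 8) {
  stopifnot(duration_s > 0)
  structure(list(start_s = start_s, duration_s = duration_s),
            class = "response_window")
}

#' Per-trial odor response amplitudes
#'
#' Mean \eqn{\Delta F/F} over a window anchored at an odor-epoch onset, one
#' value per cell per selected trial. For transition trials, `epoch =
#' "second"` anchors the window at the second pulse onset (the convention
#' used for transition amplitudes).
#'
#' @param t a dF/F [trial_tensor()] (unfiltered).
#' @param schedule a [stim_schedule()].
#' @param epoch `"first"`, `"second"`, or `"last"` odor epoch of each trial.
#' @param window a [response_window()]; `NULL` means the full odor-on epoch.
#' @param stimuli optional character vector restricting to these stimulus ids.
#' @return tibble with columns `cell`, `trial`, `stimulus`, `amplitude`.
#' @export
response_amplitude <- function(t, schedule, epoch = "first", window = NULL,
                               stimuli = NULL) {
  check_quantifiable(t)
  trials <- seq_len(n_trials(t))
  if (!is.null(stimuli)) trials <- trials[t$trial_labels[trials] %in% stimuli]
  if (length(trials) == 0) stop("no trials selected", call. = FALSE)
  purrr::map_dfr(trials, function(tr) {
    ep <- schedule_epoch(schedule, tr, epoch)
    if (is.null(window)) {
      a <- ep$onset_s; b <- ep$offset_s
    } else {
      a <- ep$onset_s + window$start_s
      b <- a + window$duration_s
    }
    idx <- window_frames(a, b, t$frame_rate_hz, n_frames(t))
    amp <- rowMeans(t$values[, idx, tr, drop = FALSE][, , 1, drop = FALSE])
    tibble::tibble(cell = seq_len(n_cells(t)), trial = tr,
                   stimulus = t$trial_labels[tr], amplitude = amp)
  })
}

#' Transition contrast score
#'
#' For a transition trial, the difference between the extreme
#' \eqn{\Delta F/F} values flanking the odor handoff: the maximum during the
#' second-pulse epoch minus the minimum during the first-pulse epoch. The
#' score is invariant to adding a constant to the whole trace. A large
#' positive score marks a salient boundary (recovered second response after
#' a depressed first response).
#'
#' @param t a dF/F [trial_tensor()] (unfiltered).
#' @param schedule a [stim_schedule()].
#' @param trials integer vector of transition trials; default all
#'   transitions in the schedule.
#' @param signed if `FALSE`, return the absolute value.
#' @return tibble with columns `cell`, `trial`, `stimulus`, `contrast`.
#' @export
transition_contrast <- function(t, schedule, trials = NULL, signed = TRUE) {
  check_quantifiable(t)
  tt <- transition_trials(schedule)
  if (is.null(trials)) trials <- tt$trial[tt$is_transition]
  if (length(trials) == 0) stop("no transition trials selected", call. = FALSE)
  not_tr <- setdiff(trials, tt$trial[tt$is_transition])
  if (length(not_tr) > 0)
    stop("not transition trials: ", paste(not_tr, collapse = ", "), call. = FALSE)
  purrr::map_dfr(trials, function(tr) {
    e1 <- schedule_epoch(schedule, tr, "first")
    e2 <- schedule_epoch(schedule, tr, "second")
    i1 <- window_frames(e1$onset_s, e1$offset_s, t$frame_rate_hz, n_frames(t))
    i2 <- window_frames(e2$onset_s, e2$offset_s, t$frame_rate_hz, n_frames(t))
    lo <- apply(t$values[, i1, tr, drop = FALSE], 1, min)
    hi <- apply(t$values[, i2, tr, drop = FALSE], 1, max)
    ct <- hi - lo
    if (!signed) ct <- abs(ct)
    tibble::tibble(cell = seq_len(n_cells(t)), trial = tr,
                   stimulus = t$trial_labels[tr], contrast = ct)
  })
}

#' Trial-averaged traces sorted by response to one stimulus
#'
#' Averages traces across trials within each stimulus and orders cells by
#' descending response amplitude to `sort_stimulus` (stable sort; ties keep
#' original cell order), the layout used for population heatmaps.
#'
#' @param t a dF/F [trial_tensor()] (unfiltered).
#' @param schedule a [stim_schedule()].
#' @param sort_stimulus stimulus id whose amplitudes define the row order.
#' @param epoch,window passed to [response_amplitude()] for the sort key.
#' @return an object of class `kc_heatmap`: a list with `traces` (tibble
#'   `stimulus`, `cell`, `rank`, `frame`, `t_s`, `dff`) and `cell_order`
#'   (original cell indices, best responder first).
#' @export
trial_average_sorted <- function(t, schedule, sort_stimulus, epoch = "first",
                                 window = NULL) {
  check_quantifiable(t)
  amp <- response_amplitude(t, schedule, epoch = epoch, window = window,
                            stimuli = sort_stimulus)
  key <- amp |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(amplitude = mean(.data$amplitude), .groups = "drop")
  cell_order <- key$cell[order(-key$amplitude, key$cell)]
  rank_of <- integer(n_cells(t)); rank_of[cell_order] <- seq_along(cell_order)
  stims <- unique(t$trial_labels)
  traces <- purrr::map_dfr(stims, function(st) {
    trs <- which(t$trial_labels == st)
    m <- apply(t$values[, , trs, drop = FALSE], c(1, 2), mean)
    tibble::tibble(
      stimulus = st,
      cell = rep(seq_len(n_cells(t)), times = n_frames(t)),
      rank = rep(rank_of, times = n_frames(t)),
      frame = rep(seq_len(n_frames(t)), each = n_cells(t)),
      t_s = (rep(seq_len(n_frames(t)), each = n_cells(t)) - 1) / t$frame_rate_hz,
      dff = as.vector(m)
    )
  })
  structure(list(traces = traces, cell_order = cell_order,
                 sort_stimulus = sort_stimulus),
            class = "kc_heatmap")
}

#' Project trial response vectors onto the first two principal components
#'
#' Mean-centers the trial x cell amplitude matrix and projects onto the top
#' two principal axes. Each axis is oriented so that its largest-magnitude
#' loading is positive, fixing the sign ambiguity.
#'
#' @param features tibble with columns `trial`, `stimulus`, `cell`,
#'   `feature` (per-trial per-cell response amplitudes), or a numeric
#'   trial x cell matrix.
#' @return tibble with columns `trial`, `stimulus`, `PC1`, `PC2` and
#'   attribute `var_explained`.
#' @export
pca_project <- function(features) {
  if (is.matrix(features)) {
    X <- features
    meta <- tibble::tibble(trial = seq_len(nrow(X)),
                           stimulus = rownames(X) %||% as.character(seq_len(nrow(X))))
  } else {
    wide <- features |>
      dplyr::select("trial", "stimulus", "cell", "feature") |>
      tidyr::pivot_wider(names_from = "cell", values_from = "feature")
    meta <- wide[, c("trial", "stimulus")]
    X <- as.matrix(wide[, -(1:2)])
  }
  if (nrow(X) < 3) stop("need at least 3 trials for PCA", call. = FALSE)
  if (ncol(X) < 2) stop("need at least 2 cells for PCA", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  if (k < 2 || pc$sdev[2] < 1e-12 * max(pc$sdev[1], 1e-300)) {
    warning("response matrix has rank < 2; second coordinate set to 0", call. = FALSE)
    pc2 <- rep(0, nrow(X))
    if (k == 2) pc2 <- scores[, 2] * 0
    out <- tibble::tibble(meta, PC1 = scores[, 1], PC2 = pc2)
  } else {
    out <- tibble::tibble(meta, PC1 = scores[, 1], PC2 = scores[, 2])
  }
  attr(out, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  out
}

#' Per-cell response correlation between two odors
#'
#' Pearson correlation of per-cell mean response amplitudes between two
#' stimuli, pooled over all supplied cells (across flies when a `fly`
#' column is present), with a two-sided p-value.
#'
#' @param amplitudes tibble with columns `cell`, `stimulus`, `amplitude`
#'   (and optionally `fly`; cell identities are made unique per fly).
#' @param odor_pair character vector of two stimulus ids.
#' @return tibble with `odor_x`, `odor_y`, `estimate`, `p.value`, `n_cells`.
#' @export
odor_response_correlation <- function(amplitudes, odor_pair) {
  stopifnot(length(odor_pair) == 2)
  a <- amplitudes |> dplyr::filter(.data$stimulus %in% odor_pair)
  if ("fly" %in% names(a)) {
    a$cell <- paste(a$fly, a$cell, sep = ":")
  }
  wide <- a |>
    dplyr::group_by(.data$cell, .data$stimulus) |>
    dplyr::summarise(amplitude = mean(.data$amplitude), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "stimulus", values_from = "amplitude") |>
    tidyr::drop_na()
  if (nrow(wide) < 3) stop("need at least 3 pooled cells", call. = FALSE)
  x <- wide[[odor_pair[1]]]; y <- wide[[odor_pair[2]]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in amplitude vector", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(odor_x = odor_pair[1], odor_y = odor_pair[2],
                 estimate = unname(ct$estimate), p.value = ct$p.value,
                 n_cells = nrow(wide))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
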