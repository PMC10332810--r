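#' Per-frame quadrant occupancy counts
#'
#' Counts fly centroids per quadrant for every frame. Quadrant membership
#' follows [quadrant_of()]: a fly exactly on a boundary is assigned to the
#' counter-clockwise-adjacent quadrant.
#'
#' @param traj trajectory tibble with columns `fly_id`, `frame`, `x_mm`,
#'   `y_mm` (one run).
#' @param center arena center, length-2 numeric (default from the
#'   trajectory attribute, else the origin).
#' @return tibble with columns `frame`, `q1`..`q4`, `n_total`.
#' @export
quadrant_counts <- function(traj, center = NULL) {
  center <- center %||% attr(traj, "center") %||% c(0, 0)
  q <- quadrant_of(traj$x_mm, traj$y_mm, center)
  tab <- traj |>
    dplyr::mutate(quadrant = q) |>
    dplyr::count(.data$frame, .data$quadrant) |>
    tidyr::pivot_wider(names_from = "quadrant", values_from = "n",
                       names_prefix = "q", values_fill = 0L)
  for (nm in paste0("q", 1:4)) if (!nm %in% names(tab)) tab[[nm]] <- 0L
  tab <- tab[, c("frame", paste0("q", 1:4))]
  tab$n_total <- tab$q1 + tab$q2 + tab$q3 + tab$q4
  dplyr::arrange(tab, .data$frame)
}

#' Performance-index series and summary
#'
#' Per frame, `PI(t) = (N_paired - N_unpaired) / N_total`, where the paired
#' quadrants hold the trained (paired) odor. The scalar summary is the mean
#' PI over the final 30 s of the test period (frames in
#' `[T_end - 30 s, T_end)`); when a pre-odor baseline epoch is given, its
#' mean PI is stored for baseline correction.
#'
#' @param counts output of [quadrant_counts()].
#' @param paired_quadrants integer subset of 1:4 holding the paired odor.
#' @param frame_rate_hz frames per second.
#' @param summary_window_s length of the final summary window (default 30).
#' @param baseline_frames optional integer frames making up the pre-odor
#'   baseline epoch; their mean PI is returned as `baseline_pi`.
#' @param design `"reciprocal"` or `"unpaired-control"` provenance tag.
#' @return a `pi_result` list: `pi_series` tibble (`frame`, `pi`),
#'   `pi_scalar`, `baseline_pi` (NA when no baseline), `design`.
#' @export
performance_index_series <- function(counts, paired_quadrants = c(1, 3),
                                     frame_rate_hz, summary_window_s = 30,
                                     baseline_frames = NULL,
                                     design = c("reciprocal", "unpaired-control")) {
  design <- match.arg(design)
  if (any(counts$n_total == 0)) stop("frame with zero flies", call. = FALSE)
  fav <- quadrant_membership(paired_quadrants)
  qmat <- as.matrix(counts[, paste0("q", 1:4)])
  n_paired <- rowSums(qmat[, fav, drop = FALSE])
  n_unpaired <- rowSums(qmat[, !fav, drop = FALSE])
  pi_t <- (n_paired - n_unpaired) / counts$n_total
  series <- tibble::tibble(frame = counts$frame, pi = pi_t)
  t_end <- max(counts$frame) / frame_rate_hz
  in_summary <- (counts$frame - 1) / frame_rate_hz >= t_end - summary_window_s
  baseline_pi <- NA_real_
  if (!is.null(baseline_frames))
    baseline_pi <- mean(pi_t[counts$frame %in% baseline_frames])
  structure(list(pi_series = series,
                 pi_scalar = mean(pi_t[in_summary]),
                 baseline_pi = baseline_pi, design = design),
            class = "pi_result")
}

#' @export
print.pi_result <- function(x, ...) {
  cat(sprintf("<pi_result> PI = %.3f (design: %s", x$pi_scalar, x$design))
  if (!is.na(x$baseline_pi)) cat(sprintf(", baseline %.3f", x$baseline_pi))
  cat(")\n")
  invisible(x)
}

#' Reciprocal-design performance index
#'
#' A reported discrimination score averages the PIs of two reciprocally
#' trained groups (paired/unpaired odor identities swapped), cancelling
#' innate odor bias.
#'
#' @param pi_run1,pi_run2 scalar PIs or `pi_result` objects.
#' @return the arithmetic mean of the two summary PIs.
#' @export
reciprocal_pi <- function(pi_run1, pi_run2) {
  v <- vapply(list(pi_run1, pi_run2),
              function(p) if (inherits(p, "pi_result")) p$pi_scalar else p,
              numeric(1))
  mean(v)
}

#' Generalization score with unpaired control
#'
#' Generalization tests cannot use a reciprocal design; instead the test PI
#' is compared against an unpaired control (reinforcement not paired with
#' odor), with both PIs first corrected for initial quadrant-occupancy bias
#' by subtracting their pre-odor baselines:
#' `score = (PI_test - baseline_test) - (PI_control - baseline_control)`.
#'
#' @param pi_test,pi_control `pi_result` objects carrying `baseline_pi`.
#' @return scalar generalization score.
#' @export
generalization_score <- function(pi_test, pi_control) {
  stopifnot(inherits(pi_test, "pi_result"), inherits(pi_control, "pi_result"))
  if (is.na(pi_test$baseline_pi) || is.na(pi_control$baseline_pi))
    stop("both PI results need a pre-odor baseline", call. = FALSE)
  (pi_test$pi_scalar - pi_test$baseline_pi) -
    (pi_control$pi_scalar - pi_control$baseline_pi)
}

#' Upwind displacement after stimulus onset
#'
#' For each fly, the increase in distance from the arena center relative to
#' its position at stimulus onset: `d_i(t) = r_i(t) - r_i(onset)`. The
#' arena series averages across flies; the scalar summary is the mean of
#' the arena series over the stimulus window. Flies with missing frames in
#' the window are dropped with a warning.
#'
#' @param traj trajectory tibble (`fly_id`, `frame`, `t_s`, `x_mm`, `y_mm`).
#' @param onset_s stimulus onset time, seconds.
#' @param window_s length of the stimulus window, seconds (default 30).
#' @param center arena center (default from attribute, else origin).
#' @return list with `per_fly` (tibble `fly_id`, `t_s`, `displacement_mm`),
#'   `arena_series` (tibble `t_s`, `mean_displacement_mm`), and
#'   `summary_mm` (scalar mean over the window).
#' @export
upwind_displacement <- function(traj, onset_s, window_s = 30, center = NULL) {
  center <- center %||% attr(traj, "center") %||% c(0, 0)
  rate <- attr(traj, "frame_rate_hz")
  if (is.null(rate)) {
    tsu <- sort(unique(traj$t_s))
    rate <- 1 / min(diff(tsu))
  }
  onset_frame <- floor(onset_s * rate) + 1
  if (!any(traj$frame == onset_frame))
    stop("stimulus onset outside the recording", call. = FALSE)
  win <- traj$t_s >= onset_s & traj$t_s < onset_s + window_s
  d <- traj |>
    dplyr::mutate(r = sqrt((.data$x_mm - center[1])^2 + (.data$y_mm - center[2])^2))
  r0 <- d |>
    dplyr::filter(.data$frame == onset_frame) |>
    dplyr::select("fly_id", r0 = "r")
  full_n <- sum(win) / length(unique(traj$fly_id))
  per_fly <- d[win, ] |>
    dplyr::inner_join(r0, by = "fly_id") |>
    dplyr::mutate(displacement_mm = .data$r - .data$r0) |>
    dplyr::select("fly_id", "frame", "t_s", "displacement_mm")
  complete <- per_fly |>
    dplyr::count(.data$fly_id) |>
    dplyr::filter(.data$n == max(.data$n))
  if (nrow(complete) < length(unique(traj$fly_id)))
    warning("flies with missing frames dropped from upwind displacement",
            call. = FALSE)
  per_fly <- per_fly |> dplyr::semi_join(complete, by = "fly_id")
  arena <- per_fly |>
    dplyr::group_by(.data$t_s) |>
    dplyr::summarise(mean_displacement_mm = mean(.data$displacement_mm),
                     .groups = "drop")
  list(per_fly = per_fly, arena_series = arena,
       summary_mm = mean(arena$mean_displacement_mm))
}

#' Radial positions at a time point
#'
#' Distance of every fly from the arena center at time `t`, with the arena
#' mean; used as the starting-position control when comparing upwind
#' responses across stimulus conditions.
#'
#' @param traj trajectory tibble.
#' @param t time in seconds.
#' @param center arena center (default from attribute, else origin).
#' @return list with `per_fly` (tibble `fly_id`, `r_mm`) and `mean_mm`.
#' @export
radial_position_at <- function(traj, t, center = NULL) {
  center <- center %||% attr(traj, "center") %||% c(0, 0)
  rate <- attr(traj, "frame_rate_hz")
  fr <- if (is.null(rate)) {
    tsu <- sort(unique(traj$t_s))
    unique(traj$frame[abs(traj$t_s - tsu[which.min(abs(tsu - t))]) < 1e-9])[1]
  } else floor(t * rate) + 1
  rows <- traj[traj$frame == fr, ]
  if (nrow(rows) == 0) stop("time outside the recording", call. = FALSE)
  per_fly <- tibble::tibble(
    fly_id = rows$fly_id,
    r_mm = sqrt((rows$x_mm - center[1])^2 + (rows$y_mm - center[2])^2))
  list(per_fly = per_fly, mean_mm = mean(per_fly$r_mm))
}

#' Estimate the upwind drift from paired stimulated / control runs
#'
#' Recovers the stimulus-conditioned radial drift (mm/s) by comparing
#' per-frame radial increments between a stimulated run and a control run
#' generated with the same seed and noise (common random numbers), over a
#' short window right after stimulus onset. Only increments where both
#' flies sit in an annulus away from the arena wall and center are used:
#' reflection at the wall partially cancels outward drift, and close to
#' the center the curvature of the radial coordinate biases increment
#' differences once the paired trajectories diverge. Keeping the window
#' short (default 1 s) keeps that divergence, and hence the bias, small.
#'
#' @param stim_traj,control_traj frame-aligned trajectory tibbles from
#'   [gen_arena_trajectories()] (same flies, same seed; the control run
#'   has no stimulus epoch).
#' @param onset_s stimulus onset time, seconds.
#' @param window_s estimation window after onset (default 1).
#' @param r_range annulus of admissible radii, mm (default `c(10, 40)`
#'   for the standard 50 mm arena).
#' @return list with `drift_mm_s`, `se`, `n_increments`.
#' @export
estimate_upwind_drift <- function(stim_traj, control_traj, onset_s,
                                  window_s = 1, r_range = c(10, 40)) {
  rate <- attr(stim_traj, "frame_rate_hz")
  if (is.null(rate)) stop("trajectories need a frame_rate_hz attribute", call. = FALSE)
  r_of <- function(traj) {
    ctr <- attr(traj, "center") %||% c(0, 0)
    m <- matrix(sqrt((traj$x_mm - ctr[1])^2 + (traj$y_mm - ctr[2])^2),
                ncol = length(unique(traj$fly_id)))
    m
  }
  r1 <- r_of(stim_traj); r0 <- r_of(control_traj)
  if (!all(dim(r1) == dim(r0)))
    stop("stimulated and control runs must be frame-aligned", call. = FALSE)
  first <- floor(onset_s * rate) + 1L
  nin <- max(1L, as.integer(round(window_s * rate)))
  rows <- first:min(first + nin, nrow(r1))
  d <- diff(r1[rows, , drop = FALSE]) - diff(r0[rows, , drop = FALSE])
  keep <- (r1[rows, , drop = FALSE] > r_range[1] & r1[rows, , drop = FALSE] < r_range[2] &
           r0[rows, , drop = FALSE] > r_range[1] & r0[rows, , drop = FALSE] < r_range[2])
  keep <- keep[seq_len(nrow(d)), , drop = FALSE]
  vals <- d[keep]
  if (length(vals) == 0) stop("no admissible increments in the window", call. = FALSE)
  list(drift_mm_s = mean(vals) * rate,
       se = stats::sd(vals) * rate / sqrt(length(vals)),
       n_increments = length(vals))
}
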