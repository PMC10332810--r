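#' Write / read arena trajectories as CSV
#'
#' Plain CSV with columns `run_id, fly_id, frame, t_s, x_mm, y_mm`; arena
#' geometry travels in a JSON side-car (`<path>.meta.json`) so a read
#' round-trips the attributes.
#'
#' @param traj trajectory tibble from [gen_arena_trajectories()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  readr::write_csv(traj[, c("run_id", "fly_id", "frame", "t_s", "x_mm", "y_mm")],
                   path)
  meta <- list(arena_radius = attr(traj, "arena_radius"),
               center = attr(traj, "center"),
               frame_rate_hz = attr(traj, "frame_rate_hz"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  traj <- readr::read_csv(path, show_col_types = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(traj, "arena_radius") <- meta$arena_radius
    attr(traj, "center") <- meta$center
    attr(traj, "frame_rate_hz") <- meta$frame_rate_hz
  }
  traj
}

#' Write / read a decoding feature table as CSV
#'
#' Columns (`fly`,) `trial`, `stimulus`, `cell`, `feature`.
#'
#' @param features feature tibble (e.g. from [kc_feature_table()]).
#' @param path CSV file path.
#' @return `path` invisibly / the tibble.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) readr::read_csv(path, show_col_types = FALSE)

#' Write / read a trial tensor bundle
#'
#' A directory holding `meta.json` (frame rate, kind, background, trial
#' labels, provenance flags), `values.csv` (long table `cell`, `frame`,
#' `trial`, `value`), and optionally `schedule.csv`. A plain-text container
#' that round-trips a [trial_tensor()] plus its [stim_schedule()].
#'
#' @param t a [trial_tensor()].
#' @param dir directory to create.
#' @param schedule optional [stim_schedule()].
#' @return `dir` invisibly / a list with `tensor` and `schedule`.
#' @export
write_tensor_bundle <- function(t, dir, schedule = NULL) {
  stopifnot(inherits(t, "trial_tensor"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(frame_rate_hz = t$frame_rate_hz, kind = t$kind,
               background = t$background,
               background_subtracted = t$background_subtracted,
               filtered = t$filtered, trial_labels = t$trial_labels,
               dim = dim(t$values))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  d <- dim(t$values)
  long <- tibble::tibble(
    cell = rep(seq_len(d[1]), times = d[2] * d[3]),
    frame = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    trial = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(t$values))
  readr::write_csv(long, file.path(dir, "values.csv"))
  if (!is.null(schedule))
    readr::write_csv(as.data.frame(schedule), file.path(dir, "schedule.csv"))
  invisible(dir)
}

#' @rdname write_tensor_bundle
#' @export
read_tensor_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  long <- readr::read_csv(file.path(dir, "values.csv"), show_col_types = FALSE)
  d <- as.integer(meta$dim)
  vals <- array(NA_real_, dim = d)
  vals[cbind(long$cell, long$frame, long$trial)] <- long$value
  t <- trial_tensor(vals, meta$frame_rate_hz, kind = meta$kind,
                    trial_labels = meta$trial_labels,
                    background = meta$background)
  t$background_subtracted <- isTRUE(meta$background_subtracted)
  t$filtered <- isTRUE(meta$filtered)
  schedule <- NULL
  sp <- file.path(dir, "schedule.csv")
  if (file.exists(sp)) {
    s <- readr::read_csv(sp, show_col_types = FALSE)
    schedule <- stim_schedule(s$trial, s$stimulus, s$epoch, s$odor,
                              s$onset_s, s$offset_s)
  }
  list(tensor = t, schedule = schedule)
}
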